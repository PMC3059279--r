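#' Construct a cardiac-gated MOLLI sampling scheme
#'
#' A MOLLI (modified Look-Locker inversion recovery) acquisition merges
#' single-shot images from several inversion experiments, acquired one per
#' heartbeat. Three standard layouts are provided:
#'
#' * `"classic"`: 3 inversions sampling 3, 3 and 5 beats (11 images);
#' * `"hybrid_pre"`: 2 inversions sampling 5 and 1 beats (6 images), the
#'   shortened scheme used for long pre-contrast T1 (~950-1500 msec);
#' * `"hybrid_post"`: 3 inversions sampling 4, 2 and 1 beats (7 images),
#'   used for short post-contrast T1 (~500 msec or less), front-loading
#'   samples onto the fast early recovery.
#'
#' All three use an initial effective inversion time of 90 msec, an 80 msec
#' per-inversion increment, and 3 dummy recovery beats between inversions.
#'
#' @param kind one of `"classic"`, `"hybrid_pre"`, `"hybrid_post"`.
#' @return object of class `molli_scheme`.
#' @examples
#' molli_scheme("classic")
#' @seealso [new_molli_scheme()] for arbitrary layouts, [ti_schedule()],
#'   [breath_hold_beats()]
#' @export
molli_scheme <- function(kind = c("classic", "hybrid_pre", "hybrid_post")) {
  kind <- match.arg(kind)
  spi <- switch(kind,
    classic = c(3L, 3L, 5L),
    hybrid_pre = c(5L, 1L),
    hybrid_post = c(4L, 2L, 1L)
  )
  new_molli_scheme(kind, spi, dummy_beats_between = 3L, ti0_msec = 90, dti_msec = 80)
}

#' Construct an arbitrary MOLLI sampling scheme
#'
#' @param name label for the scheme.
#' @param samples_per_inversion ordered vector of positive image counts, one
#'   per inversion group.
#' @param dummy_beats_between non-negative number of recovery beats between
#'   inversion pulses.
#' @param ti0_msec initial effective inversion time (msec, `> 0`).
#' @param dti_msec per-inversion-group increment of the effective inversion
#'   time (msec, `>= 0`).
#' @return object of class `molli_scheme`.
#' @export
new_molli_scheme <- function(name, samples_per_inversion, dummy_beats_between = 3L,
                             ti0_msec = 90, dti_msec = 80) {
  spi <- as.integer(samples_per_inversion)
  if (length(spi) < 1 || any(spi < 1)) stop("need at least one inversion group with positive counts")
  if (dummy_beats_between < 0) stop("`dummy_beats_between` must be non-negative")
  if (ti0_msec <= 0) stop("`ti0_msec` must be positive")
  if (dti_msec < 0) stop("`dti_msec` must be non-negative")
  structure(
    list(name = name, samples_per_inversion = spi,
         dummy_beats_between = as.integer(dummy_beats_between),
         ti0_msec = ti0_msec, dti_msec = dti_msec),
    class = "molli_scheme"
  )
}

#' @export
print.molli_scheme <- function(x, ...) {
  cat("MOLLI scheme `", x$name, "`: ",
      paste(x$samples_per_inversion, collapse = "+"),
      " sampling (", sum(x$samples_per_inversion), " images), TIeff0 ",
      x$ti0_msec, " msec + ", x$dti_msec, " msec/inversion, ",
      x$dummy_beats_between, " dummy beats\n", sep = "")
  invisible(x)
}

#' Total images acquired by a scheme
#' @param scheme a [molli_scheme()].
#' @return integer image count.
#' @export
total_images <- function(scheme) {
  stopifnot(inherits(scheme, "molli_scheme"))
  sum(scheme$samples_per_inversion)
}

#' Effective inversion-time schedule at a given heart rate
#'
#' In a gated MOLLI acquisition, one single-shot image is acquired each
#' heartbeat after an inversion pulse, so within an inversion group the
#' effective inversion times grow by one R-R interval per beat. Group g
#' (0-based) starts at `ti0 + g * dti`; image k (0-based) within the group
#' is read at `ti0 + g * dti + k * rr`.
#'
#' @param scheme a [molli_scheme()].
#' @param rr_msec cardiac period in msec, in `[300, 2000]` (200 down to
#'   30 bpm).
#' @return data frame of class `ti_schedule` with columns `inversion`
#'   (0-based group), `beat` (0-based within group), `ti_eff_msec`, in
#'   acquisition order; attribute `rr_msec`.
#' @examples
#' ti_schedule(molli_scheme("classic"), rr_msec = rr_from_hr(68))
#' @export
ti_schedule <- function(scheme, rr_msec) {
  stopifnot(inherits(scheme, "molli_scheme"))
  if (!is.numeric(rr_msec) || length(rr_msec) != 1 || rr_msec < 300 || rr_msec > 2000)
    stop("`rr_msec` must be a single value in [300, 2000] msec")
  spi <- scheme$samples_per_inversion
  rows <- do.call(rbind, lapply(seq_along(spi) - 1L, function(g) {
    k <- seq_len(spi[g + 1L]) - 1L
    data.frame(inversion = g, beat = k,
               ti_eff_msec = scheme$ti0_msec + g * scheme$dti_msec + k * rr_msec)
  }))
  attr(rows, "rr_msec") <- rr_msec
  class(rows) <- c("ti_schedule", "data.frame")
  rows
}

#' Breath-hold length of a scheme in heartbeats
#'
#' Imaged beats plus the dummy recovery beats separating inversion pulses;
#' the quantity the shortened hybrid schemes were designed to reduce.
#'
#' @param scheme a [molli_scheme()].
#' @return heartbeat count.
#' @examples
#' breath_hold_beats(molli_scheme("classic"))    # 17
#' breath_hold_beats(molli_scheme("hybrid_pre")) # 9
#' @export
breath_hold_beats <- function(scheme) {
  stopifnot(inherits(scheme, "molli_scheme"))
  n_groups <- length(scheme$samples_per_inversion)
  sum(scheme$samples_per_inversion) + scheme$dummy_beats_between * (n_groups - 1L)
}

#' Cardiac period from heart rate
#' @param hr_bpm heart rate in beats per minute.
#' @return R-R interval in msec (`60000 / hr_bpm`).
#' @export
rr_from_hr <- function(hr_bpm) {
  if (any(hr_bpm <= 0)) stop("`hr_bpm` must be positive")
  60000 / hr_bpm
}
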