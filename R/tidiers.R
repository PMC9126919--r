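#' Broom-style tidiers
#'
#' `tidy()` returns the per-parcel table of a result object; `glance()`
#' returns a one-row model-level summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @method tidy transformation_result
#' @export
tidy.transformation_result <- function(x, ...) x$parcels

#' @rdname tidiers
#' @method glance transformation_result
#' @export
glance.transformation_result <- function(x, ...) {
  p <- x$parcels
  tibble::tibble(
    n_parcels = nrow(p),
    n_reliable = sum(p$in_reliability_mask),
    n_positive_t = sum(p$positive_t),
    mean_mr = mean(p$mr),
    mean_rr = mean(p$rr),
    mean_t = mean(p$t_score)
  )
}

#' @rdname tidiers
#' @method tidy link_result
#' @export
tidy.link_result <- function(x, ...) x$parcels

#' @rdname tidiers
#' @method glance link_result
#' @export
glance.link_result <- function(x, ...) {
  p <- x$parcels
  tibble::tibble(
    n_parcels_tested = nrow(p),
    n_significant = sum(p$significant, na.rm = TRUE),
    n_positive = sum(p$significant & p$direction == "POSITIVE",
                     na.rm = TRUE),
    n_negative = sum(p$significant & p$direction == "NEGATIVE",
                     na.rm = TRUE),
    mean_subject_r = mean(p$mean_r, na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @method tidy reinstatement_result
#' @export
tidy.reinstatement_result <- function(x, ...) x$parcels

#' @rdname tidiers
#' @method glance reinstatement_result
#' @export
glance.reinstatement_result <- function(x, ...) {
  m <- x$means
  tibble::tibble(
    n_subjects = length(unique(m$subject_id)),
    n_parcels = length(unique(m$parcel_id)),
    mean_r_precise = mean(m$mean_r[m$condition == "PRECISE"]),
    mean_r_summary = mean(m$mean_r[m$condition == "SUMMARY"]),
    n_sig_precise = sum(x$parcels$sig_precise, na.rm = TRUE),
    n_sig_summary = sum(x$parcels$sig_summary, na.rm = TRUE)
  )
}
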