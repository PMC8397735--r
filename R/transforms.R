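#' Forward variable transform
#'
#' Maps a climate variable to the unbounded scale the per-pixel regressions
#' are fit on: identity for temperature, natural log for precipitation
#' (positive rates), logit for cloud cover fractions in (0, 1).
#'
#' @param values numeric values on the natural scale.
#' @param kind "identity", "log" or "logit".
#' @param context optional string prefixed to domain-error messages
#'   (e.g. pixel/epoch coordinates).
#' @return transformed numeric values.
#' @export
transformValues <- function(values, kind = c("identity", "log", "logit"),
                            context = "") {
  kind <- match.arg(kind)
  bad <- switch(kind,
                identity = rep(FALSE, length(values)),
                log = values <= 0,
                logit = values <= 0 | values >= 1)
  bad[is.na(values)] <- FALSE
  if (any(bad)) {
    where <- utils::head(which(bad), 3L)
    stop(sprintf("%s%d value(s) outside the %s domain (first at index %s: %s)",
                 if (nzchar(context)) paste0(context, ": ") else "",
                 sum(bad), kind, paste(where, collapse = ","),
                 paste(signif(values[where], 4), collapse = ",")))
  }
  switch(kind,
         identity = values,
         log = log(values),
         logit = log(values / (1 - values)))
}

#' Inverse variable transform
#'
#' Maps transformed-scale values back to the natural scale.  Defined on all
#' of the real line; the outputs respect the physical bounds strictly
#' (exp > 0, logistic in (0, 1)).
#'
#' @param values numeric transformed values.
#' @param kind "identity", "log" or "logit".
#' @return natural-scale numeric values.
#' @export
inverseTransform <- function(values, kind = c("identity", "log", "logit")) {
  kind <- match.arg(kind)
  switch(kind,
         identity = values,
         log = exp(values),
         logit = stats::plogis(values))
}
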