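#' Ordered aortic-stenosis severity levels
#'
#' Severity is graded from the echocardiographic peak aortic jet velocity:
#' mild below 3.0 m/s, moderate 3.0--4.0 m/s, severe above 4.0 m/s, with
#' `control` denoting no aortic stenosis. The order is clinical:
#' control < mild < moderate < severe.
#'
#' @return Character vector of the four severity labels in increasing order.
#' @export
#' @examples
#' severity_levels()
severity_levels <- function() {
  c("control", "mild", "moderate", "severe")
}

#' Severity factor from labels
#'
#' @param x character vector of severity labels.
#' @return Ordered factor over [severity_levels()].
#' @export
as_severity <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), severity_levels())
  if (length(bad)) {
    stop("unknown severity label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = severity_levels(), ordered = TRUE)
}

#' Diagnostic cut-off scheme for the Ao:LV ratio
#'
#' Two operating points on the ratio scale: `any_as_cutoff` flags aortic
#' stenosis of any severity (default 0.86, i.e. aortic signal below 86% of
#' LV signal), `severe_cutoff` flags severe stenosis (default 0.58). Both
#' rules call disease when the ratio is *strictly below* the cut-off, so a
#' ratio exactly at a cut-off falls in the less-diseased class.
#'
#' @param any_as_cutoff ratio below which any-severity AS is called.
#' @param severe_cutoff ratio below which severe AS is called.
#' @return An object of class `cutoff_scheme`.
#' @export
#' @examples
#' cutoff_scheme()
cutoff_scheme <- function(any_as_cutoff = 0.86, severe_cutoff = 0.58) {
  if (!(is.numeric(any_as_cutoff) && is.numeric(severe_cutoff))) {
    stop("cut-offs must be numeric")
  }
  if (!(severe_cutoff > 0 && severe_cutoff < any_as_cutoff)) {
    stop("require 0 < severe_cutoff < any_as_cutoff")
  }
  structure(
    list(any_as_cutoff = any_as_cutoff, severe_cutoff = severe_cutoff),
    class = "cutoff_scheme"
  )
}

#' Classify a measured Ao:LV ratio
#'
#' Applies the two-cut-off rule: ratio < severe cut-off gives `severe_AS`;
#' ratio in \[severe cut-off, any-AS cut-off) gives `non_severe_AS`; ratio at
#' or above the any-AS cut-off gives `no_AS`. Boundary values go to the
#' less-diseased class because the operating rule is a strict `<`.
#'
#' @param ratio positive Ao:LV ratio(s).
#' @param scheme a [cutoff_scheme()].
#' @return factor with levels `no_AS`, `non_severe_AS`, `severe_AS`.
#' @export
#' @examples
#' classify_severity(c(0.36, 0.70, 1.29))
classify_severity <- function(ratio, scheme = cutoff_scheme()) {
  if (!inherits(scheme, "cutoff_scheme")) stop("scheme must be a cutoff_scheme")
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be finite and > 0")
  }
  cls <- ifelse(ratio < scheme$severe_cutoff, "severe_AS",
                ifelse(ratio < scheme$any_as_cutoff, "non_severe_AS", "no_AS"))
  factor(cls, levels = c("no_AS", "non_severe_AS", "severe_AS"))
}
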