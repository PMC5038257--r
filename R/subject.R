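## Subject domain type: covariates + derived fat-free mass for one individual.

#' Construct and validate a subject
#'
#' A subject bundles the covariates used by the pharmacokinetic models: sex,
#' body weight and height (from which fat-free mass is derived), HIV-1
#' serostatus and antiretroviral class, plus any extra covariates used by the
#' exposure-response analysis (age, albumin, total protein, CD4 category,
#' alcohol intake, diabetes, previous isoniazid treatment).
#'
#' Invariants: `weight > 0`, `0.5 < height < 2.5` m, and `art_class != "none"`
#' implies `hiv_positive`.
#'
#' @param id subject identifier (coerced to character).
#' @param sex `"male"` or `"female"`.
#' @param weight body weight, kg.
#' @param height height, m.
#' @param hiv_positive logical HIV-1 serostatus.
#' @param art_class `"none"`, `"nnrti"`, or `"pi_lpvr"`.
#' @param ... extra named covariates (e.g. `age`, `albumin`, `alcohol`).
#' @return a list of class `tbpk_subject`.
#' @export
subject <- function(id, sex, weight, height, hiv_positive = FALSE,
                    art_class = c("none", "nnrti", "pi_lpvr"), ...) {
  sex <- match.arg(sex, c("male", "female"))
  art_class <- match.arg(art_class)
  if (!is.numeric(weight) || weight <= 0) stop("weight must be positive")
  if (!is.numeric(height) || height <= 0.5 || height >= 2.5) {
    stop("height must be in (0.5, 2.5) m")
  }
  hiv_positive <- isTRUE(hiv_positive)
  if (art_class != "none" && !hiv_positive) {
    stop("art_class != 'none' requires hiv_positive")
  }
  s <- c(list(id = as.character(id), sex = sex, weight = weight,
              height = height, hiv_positive = hiv_positive,
              art_class = art_class,
              ffm = fat_free_mass(sex, weight, height)),
         list(...))
  structure(s, class = "tbpk_subject")
}

#' @export
print.tbpk_subject <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %.1f kg, %.2f m (FFM %.1f kg), HIV%s, ART=%s\n",
              x$id, x$sex, x$weight, x$height, x$ffm,
              if (x$hiv_positive) "+" else "-", x$art_class))
  invisible(x)
}

## Coerce a tbpk_subject, plain list, or one-row data.frame to a subject list
as_subject <- function(x) {
  if (inherits(x, "tbpk_subject")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("expected a single subject (one row)")
    x <- as.list(x)
  }
  if (!is.list(x)) stop("cannot interpret subject")
  if (is.null(x$ffm) && !is.null(x$sex) && !is.null(x$weight) && !is.null(x$height)) {
    x$ffm <- fat_free_mass(x$sex, x$weight, x$height)
  }
  x
}
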