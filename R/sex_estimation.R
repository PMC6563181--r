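# Sex estimation from sternal measurements: the nine published
# discriminant functions, Fisher two-group refitting, leave-one-out
# validation, and the sex-difference t test.

#' Construct a discriminant function
#'
#' A linear discriminant of sternal variables: score =
#' sum(coefficients * values) + constant.  Scores above the sectioning
#' point classify as male, below as female.
#'
#' @param variables character vector of variable names from
#'   `M, MW, B, CSW1, CSW2, CL, SI, SA`.
#' @param coefficients unstandardized coefficients (same length).
#' @param constant additive constant.
#' @param sectioning_point score threshold separating the sexes.
#' @param name label.
#' @param details optional list of extra metadata.
#' @return object of class `discriminant_function`.
#' @export
discriminant_function <- function(variables, coefficients, constant,
                                  sectioning_point,
                                  name = paste(variables, collapse = "_"),
                                  details = NULL) {
  variables <- as.character(variables)
  allowed <- c(MEASURES, "CL", "SI", "SA")
  if (!all(variables %in% allowed))
    stop("variables must be among: ", paste(allowed, collapse = ", "))
  if (length(coefficients) != length(variables))
    stop("coefficient count must equal variable count")
  structure(list(name = name, variables = variables,
                 coefficients = as.numeric(coefficients),
                 constant = as.numeric(constant),
                 sectioning_point = as.numeric(sectioning_point),
                 orientation = "male_above", details = details),
            class = "discriminant_function")
}

#' The nine published sternal discriminant functions
#'
#' Returns the published unstandardized coefficients, constants and
#' sectioning points for sex estimation from sternal measurements and
#' indices, exactly as printed: one three-variable function
#' (`MW`, `B`, `CSW1`), six single-measurement functions and two index
#' functions.  Shipped as a versioned JSON resource under
#' `inst/extdata/`.
#'
#' @return named list of nine [discriminant_function()] objects.
#' @examples
#' fns <- builtin_functions()
#' fns$B$coefficients   # 1.008
#' @export
builtin_functions <- function() {
  path <- system.file("extdata", "discriminant_functions.json",
                      package = "sternometry")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw$functions, function(f)
    discriminant_function(unlist(f$variables), unlist(f$coefficients),
                          f$constant, f$sectioning_point, name = f$name,
                          details = list(rate_male = f$rate_male,
                                         rate_female = f$rate_female,
                                         rate_overall = f$rate_overall)))
  stats::setNames(out, vapply(out, function(f) f$name, ""))
}

record_values <- function(record, variables) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  record <- unlist(record)
  vals <- suppressWarnings(as.numeric(record[variables]))
  missing <- variables[is.na(vals)]
  if (length(missing) > 0)
    stop("record is missing variable(s): ", paste(missing, collapse = ", "))
  vals
}

#' Score a record with a discriminant function
#'
#' @param f a [discriminant_function()].
#' @param record named vector, list or one-row data frame holding all of
#'   the function's variables (measurements in cm, indices as computed by
#'   [compute_indices()]).
#' @return numeric discriminant score.
#' @examples
#' score_function(builtin_functions()$B, c(B = 9.676 / 1.008))  # 0
#' @export
score_function <- function(f, record) {
  stopifnot(inherits(f, "discriminant_function"))
  sum(f$coefficients * record_values(record, f$variables)) + f$constant
}

#' Classify sex from a discriminant score
#'
#' Scores above the sectioning point classify as male, below as female;
#' a score exactly at the point is `"indeterminate"` unless `ties`
#' overrides it.
#'
#' @inheritParams score_function
#' @param ties label for scores exactly at the sectioning point:
#'   `"indeterminate"` (default), `"male"` or `"female"`.
#' @return `"male"`, `"female"` or `"indeterminate"`.
#' @export
classify_sex <- function(f, record,
                         ties = c("indeterminate", "male", "female")) {
  ties <- match.arg(ties)
  s <- score_function(f, record)
  if (s > f$sectioning_point) "male"
  else if (s < f$sectioning_point) "female"
  else ties
}

#' Fit a two-group Fisher discriminant function
#'
#' Classic two-group linear discriminant: the coefficient vector is
#' proportional to the inverse pooled within-group covariance times the
#' mean difference, scaled so the pooled within-group score variance is
#' one; the constant centers the grand-mean score at zero; the sectioning
#' point is the unweighted midpoint of the two group mean scores (equal
#' priors, as customary in osteometric work; set `prior_weighted = TRUE`
#' for a sample-size-weighted point).  Orientation is normalized so the
#' male mean score exceeds the female mean score.
#'
#' @param records data frame with a `sex` column (`"male"`/`"female"`)
#'   and the candidate variables.
#' @param variables character vector of variable names to use.
#' @param prior_weighted use sample-size-weighted sectioning point.
#' @return a [discriminant_function()] with fitting details (group mean
#'   scores, n per group) in `$details`.
#' @export
fit_discriminant <- function(records, variables, prior_weighted = FALSE) {
  stopifnot(is.data.frame(records), "sex" %in% names(records))
  sex <- records$sex
  if (!all(sex %in% c("male", "female")))
    stop("sex column must contain only 'male' and 'female'")
  X <- as.matrix(records[, variables, drop = FALSE])
  if (any(!is.finite(X))) stop("variables contain missing values")
  nm <- sum(sex == "male"); nf <- sum(sex == "female")
  if (nm < 2 || nf < 2)
    stop("need at least two records per sex (got ", nm, " male, ",
         nf, " female)")
  Xm <- X[sex == "male", , drop = FALSE]
  Xf <- X[sex == "female", , drop = FALSE]
  Sw <- (crossprod(sweep(Xm, 2, colMeans(Xm))) +
           crossprod(sweep(Xf, 2, colMeans(Xf)))) / (nm + nf - 2)
  ok <- tryCatch({ Swi <- solve(Sw); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("pooled within-group covariance is singular")
  dm <- colMeans(Xm) - colMeans(Xf)
  a <- drop(Swi %*% dm)
  s2 <- drop(t(a) %*% Sw %*% a)     # within-group score variance
  if (s2 < 1e-12) {
    warning("groups are not separated; discriminant direction is ",
            "degenerate")
    s2 <- 1e-12
  }
  a <- a / sqrt(s2)
  grand <- colMeans(X)
  const <- -sum(a * grand)
  mu_m <- sum(a * colMeans(Xm)) + const
  mu_f <- sum(a * colMeans(Xf)) + const
  if (mu_m < mu_f) {                 # normalize orientation: males above
    a <- -a; const <- -const
    tmp <- mu_m; mu_m <- mu_f; mu_f <- tmp
  }
  point <- if (prior_weighted)
    (nm * mu_m + nf * mu_f) / (nm + nf) else (mu_m + mu_f) / 2
  discriminant_function(
    variables, a, const, point,
    name = paste(variables, collapse = "_"),
    details = list(mean_score_male = mu_m, mean_score_female = mu_f,
                   n_male = nm, n_female = nf,
                   separation = mu_m - mu_f))
}

apply_function_rates <- function(f, records, ties) {
  pred <- vapply(seq_len(nrow(records)), function(i)
    classify_sex(f, records[i, , drop = FALSE], ties = ties), "")
  truth <- records$sex
  rate <- function(g) {
    n <- sum(truth == g)
    if (n == 0) NA_real_ else 100 * sum(pred == g & truth == g) / n
  }
  nm <- sum(truth == "male"); nf <- sum(truth == "female")
  rm_ <- rate("male"); rf <- rate("female")
  overall <- (nm * ifelse(is.na(rm_), 0, rm_) +
                nf * ifelse(is.na(rf), 0, rf)) / (nm + nf)
  list(rate_male = rm_, rate_female = rf, rate_overall = overall,
       n_male = nm, n_female = nf, predictions = pred)
}

#' Classification report with optional leave-one-out validation
#'
#' When `variables` are given, a discriminant function is refit for each
#' left-out record on the remaining n - 1 and used to classify it
#' (leave-one-out rule); when a fixed [discriminant_function()] is given
#' it is applied directly (plain application, no refitting).
#'
#' @param records labeled data frame (see [fit_discriminant()]).
#' @param variables_or_function character vector of variables (refit
#'   mode) or a `discriminant_function` (fixed mode).
#' @param ties tie policy passed to [classify_sex()].
#' @param prior_weighted passed to [fit_discriminant()] in refit mode.
#' @return object of class `classification_report`: per-sex and overall
#'   correct-classification rates (percent), n per sex, and the
#'   validation mode.
#' @export
loocv_classification <- function(records, variables_or_function,
                                 ties = "indeterminate",
                                 prior_weighted = FALSE) {
  if (inherits(variables_or_function, "discriminant_function")) {
    res <- apply_function_rates(variables_or_function, records, ties)
    mode <- "fixed"
  } else {
    vars <- variables_or_function
    pred <- vapply(seq_len(nrow(records)), function(i) {
      f <- fit_discriminant(records[-i, , drop = FALSE], vars,
                            prior_weighted)
      classify_sex(f, records[i, , drop = FALSE], ties = ties)
    }, "")
    truth <- records$sex
    nm <- sum(truth == "male"); nf <- sum(truth == "female")
    rm_ <- if (nm) 100 * sum(pred == "male" & truth == "male") / nm else NA
    rf <- if (nf) 100 * sum(pred == "female" & truth == "female") / nf else NA
    res <- list(rate_male = rm_, rate_female = rf,
                rate_overall = (nm * ifelse(is.na(rm_), 0, rm_) +
                                  nf * ifelse(is.na(rf), 0, rf)) / (nm + nf),
                n_male = nm, n_female = nf, predictions = pred)
    mode <- "leave-one-out"
  }
  structure(c(res, list(mode = mode)), class = "classification_report")
}

#' Resubstitution classification report for a fitted function
#'
#' @inheritParams loocv_classification
#' @param f a [discriminant_function()].
#' @return `classification_report` (mode `"resubstitution"`).
#' @export
resubstitution_classification <- function(records, f,
                                          ties = "indeterminate") {
  res <- apply_function_rates(f, records, ties)
  structure(c(res, list(mode = "resubstitution")),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> %s\n  male %.1f%% (n=%d), ",
                     "female %.1f%% (n=%d), overall %.1f%%\n"),
              x$mode, x$rate_male, x$n_male, x$rate_female, x$n_female,
              x$rate_overall))
  invisible(x)
}

#' @export
print.discriminant_function <- function(x, ...) {
  cat("<discriminant_function>",
      paste(sprintf("%.3f x %s", x$coefficients, x$variables),
            collapse = " + "),
      sprintf("%+.3f", x$constant),
      sprintf("\n  sectioning point %.4f (> male, < female)\n",
              x$sectioning_point))
  invisible(x)
}

#' Two-sample t test for sexual dimorphism of one variable
#'
#' Pooled-variance (Student) two-sample t test by default, with Welch's
#' unequal-variance form available via `welch = TRUE`.
#'
#' @param records labeled data frame (see [fit_discriminant()]).
#' @param variable variable name to test.
#' @param welch use Welch's t test instead of the pooled-variance form.
#' @return list with `t`, `p` (two-sided), `df`, `n_male`, `n_female`.
#' @export
sex_difference_test <- function(records, variable, welch = FALSE) {
  x <- records[[variable]][records$sex == "male"]
  y <- records[[variable]][records$sex == "female"]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two records per sex")
  if (!welch && stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2,
                  n_male = length(x), n_female = length(y)))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       n_male = length(x), n_female = length(y))
}
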