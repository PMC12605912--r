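#' Polynomial (curvilinear) QSPR fit of a property on one index
#'
#' Ordinary least squares of a physicochemical property on the raw powers
#' x, x^2, ..., x^degree of a topological index. The correlation coefficient
#' R is reported as the non-negative square root of R^2: for a model with a
#' negative slope the inverse relationship lives in the coefficient sign, not
#' in R. The residual standard error uses denominator n - (degree + 1), and
#' the overall p value is the upper tail of the F distribution with
#' (degree, n - degree - 1) degrees of freedom.
#'
#' @param x numeric index values.
#' @param y numeric property values, same length.
#' @param degree polynomial degree: 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return A list of class \code{qspr_fit}: \code{degree},
#'   \code{coefficients} (intercept first), \code{r}, \code{r2}, \code{se},
#'   \code{f}, \code{p_overall}, \code{n}.
#' @examples
#' fit <- fit_polynomial(1:10, 2 * (1:10) + 1, degree = 1)
#' fit$r # 1
#' @export
fit_polynomial <- function(x, y, degree) {
  stopifnot(degree %in% 1:3)
  n <- length(x)
  if (length(y) != n) {
    stop("argument error: x and y must have equal length", call. = FALSE)
  }
  if (n < degree + 2L) {
    stop(sprintf("argument error: need at least %d observations for degree %d",
                 degree + 2L, degree), call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("argument error: predictor is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singularity error: polynomial design matrix is rank-deficient",
         call. = FALSE)
  }
  names(cf) <- c("intercept", paste0("a", seq_len(degree)))
  s <- summary(fit)
  fstat <- s$fstatistic
  structure(list(
    degree = degree, coefficients = cf,
    r = sqrt(s$r.squared), r2 = s$r.squared, se = s$sigma,
    f = unname(fstat[1L]),
    p_overall = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    n = n
  ), class = "qspr_fit")
}

#' Two-predictor multiple linear regression QSPR fit
#'
#' OLS of a property on two topological indices, y = a0 + a1 x1 + a2 x2.
#' Reports the overall F test with (2, n - 3) degrees of freedom, two-sided
#' per-coefficient t tests with n - 3 degrees of freedom, and the variance
#' inflation factor of the predictor pair (both predictors share the same
#' VIF in the two-predictor case).
#'
#' @param x1,x2 numeric predictor vectors.
#' @param y numeric response vector.
#' @param names length-2 character vector naming the predictors.
#' @return A list of class \code{mlr_fit}: \code{coefficients} (intercept,
#'   then one per predictor), \code{r}, \code{r2}, \code{se}, \code{f},
#'   \code{p_overall}, \code{coef_p} (named, intercept included), \code{vif}
#'   (named, one per predictor), \code{n}.
#' @export
fit_mlr <- function(x1, x2, y, names = c("X1", "X2")) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n) {
    stop("argument error: x1, x2, y must have equal length", call. = FALSE)
  }
  if (n < 4L) {
    stop("argument error: need at least 4 observations", call. = FALSE)
  }
  v <- vif_pair(x1, x2)  # errors on perfect collinearity
  fit <- stats::lm(y ~ x1 + x2)
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", names)
  s <- summary(fit)
  fstat <- s$fstatistic
  coef_p <- s$coefficients[, 4L]
  names(coef_p) <- c("intercept", names)
  vif <- c(v, v)
  names(vif) <- names
  structure(list(
    coefficients = cf, r = sqrt(s$r.squared), r2 = s$r.squared,
    se = s$sigma, f = unname(fstat[1L]),
    p_overall = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    coef_p = coef_p, vif = vif, n = n
  ), class = "mlr_fit")
}

#' Variance inflation factor of a predictor pair
#'
#' VIF = 1 / (1 - r12^2), where r12 is the sample Pearson correlation of the
#' two predictors. With only two predictors, regressing either on the other
#' gives the same R^2 = r12^2, so both share this value.
#'
#' @param x1,x2 numeric predictor vectors, both non-constant, length >= 3.
#' @return A single number >= 1.
#' @export
vif_pair <- function(x1, x2) {
  if (length(x1) != length(x2) || length(x1) < 3L) {
    stop("argument error: need two equal-length vectors with n >= 3",
         call. = FALSE)
  }
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    stop("argument error: predictors must be non-constant", call. = FALSE)
  }
  r12 <- stats::cor(x1, x2)
  if (abs(r12) >= 1 - 1e-12) {
    stop(sprintf("singularity error: predictors perfectly collinear (r12 = %g)",
                 r12), call. = FALSE)
  }
  1 / (1 - r12^2)
}

qspr_properties <- c("MV", "P", "MR", "PSA", "ST")
qspr_indices <- c("FRZI1", "FRZI2", "SRZI", "RHM", "RF")

# the five fixed MLR predictor pairs of the reproduction
mlr_pairs <- list(
  MV = c("FRZI1", "FRZI2"), P = c("FRZI2", "RHM"), MR = c("FRZI1", "FRZI2"),
  PSA = c("FRZI2", "SRZI"), ST = c("FRZI1", "FRZI2")
)

align_tables <- function(index_table, property_table) {
  a <- index_table$drug
  b <- property_table$drug
  extra <- c(setdiff(a, b), setdiff(b, a))
  if (length(extra) > 0L) {
    stop(sprintf("alignment error: drugs not shared by both tables: %s",
                 paste(sort(unique(extra)), collapse = ", ")), call. = FALSE)
  }
  property_table[match(a, b), , drop = FALSE]
}

#' Correlation-coefficient matrix of indices against properties
#'
#' Fits one polynomial model per (index, property) pair and collects the
#' correlation coefficients R. The per-property maximum is flagged in the
#' \code{"best"} attribute.
#'
#' @param index_table data frame with a \code{drug} column and the five index
#'   columns FRZI1, FRZI2, SRZI, RHM, RF.
#' @param property_table data frame with a \code{drug} column and the five
#'   property columns MV, P, MR, PSA, ST.
#' @param model \code{"linear"}, \code{"quadratic"} or \code{"cubic"}.
#' @return A 5 x 5 numeric matrix (rows = indices, columns = properties) with
#'   a logical attribute \code{"best"} of the same shape marking each
#'   column's maximum.
#' @export
correlation_matrix <- function(index_table, property_table,
                               model = c("linear", "quadratic", "cubic")) {
  model <- match.arg(model)
  degree <- match(model, c("linear", "quadratic", "cubic"))
  property_table <- align_tables(index_table, property_table)
  props <- intersect(qspr_properties, names(property_table))
  idxs <- intersect(qspr_indices, names(index_table))
  out <- matrix(NA_real_, nrow = length(idxs), ncol = length(props),
                dimnames = list(idxs, props))
  for (i in idxs) {
    for (p in props) {
      out[i, p] <- fit_polynomial(index_table[[i]], property_table[[p]],
                                  degree)$r
    }
  }
  best <- out == matrix(apply(out, 2L, max), nrow(out), ncol(out), byrow = TRUE)
  attr(out, "best") <- best
  out
}

format_equation <- function(response, terms, coefficients, precision = 3L) {
  fmt <- function(z) {
    az <- abs(z)
    if (az != 0 && (az < 10^(-precision) || az >= 1e6)) {
      formatC(z, digits = max(precision, 2L), format = "g")
    } else {
      formatC(z, digits = precision, format = "f", drop0trailing = TRUE)
    }
  }
  rhs <- fmt(coefficients[1L])
  for (j in seq_along(terms)) {
    cj <- coefficients[j + 1L]
    rhs <- paste0(rhs, if (cj < 0) " - " else " + ", fmt(abs(cj)),
                  "[", terms[j], "]")
  }
  paste0(response, " = ", rhs)
}

fit_summary <- function(fit, equation) {
  out <- list(equation = equation,
              coefficients = as.list(fit$coefficients),
              R = fit$r, R2 = fit$r2, SE = fit$se, F = fit$f,
              p = fit$p_overall)
  if (inherits(fit, "mlr_fit")) {
    out$coef_p <- as.list(fit$coef_p)
    out$VIF <- as.list(fit$vif)
  }
  out
}

#' Best-fit QSPR report
#'
#' For every property, reports the best single-index model (highest R) at
#' each polynomial degree, plus the fixed two-index MLR model for that
#' property (MV and MR and ST on FRZI1 + FRZI2, P on FRZI2 + RHM, PSA on
#' FRZI2 + SRZI). A property with zero variance is flagged as degenerate and
#' no model is fitted for it.
#'
#' @inheritParams correlation_matrix
#' @param precision decimal places used in the formatted equation strings.
#' @return A nested list of class \code{qspr_report}: property -> model
#'   (\code{linear}, \code{quadratic}, \code{cubic}, \code{mlr}) -> list with
#'   \code{equation}, \code{index}, \code{coefficients}, \code{R}, \code{R2},
#'   \code{SE}, \code{F}, \code{p} (plus \code{coef_p}, \code{VIF} for MLR).
#' @export
best_fit_report <- function(index_table, property_table, precision = 3L) {
  property_table <- align_tables(index_table, property_table)
  props <- intersect(qspr_properties, names(property_table))
  idxs <- intersect(qspr_indices, names(index_table))
  report <- list()
  for (p in props) {
    y <- property_table[[p]]
    if (stats::var(y) == 0) {
      report[[p]] <- list(degenerate = TRUE,
                          note = "property has zero variance; no fit emitted")
      next
    }
    entry <- list()
    for (degree in 1:3) {
      fits <- lapply(idxs, function(i)
        fit_polynomial(index_table[[i]], y, degree))
      best <- which.max(vapply(fits, `[[`, numeric(1), "r"))
      fit <- fits[[best]]
      terms <- vapply(seq_len(degree), function(k) {
        if (k == 1L) idxs[best] else paste0(idxs[best], "^", k)
      }, character(1))
      fit$index <- idxs[best]
      entry[[c("linear", "quadratic", "cubic")[degree]]] <-
        c(list(index = idxs[best]),
          fit_summary(fit, format_equation(p, terms, fit$coefficients,
                                           precision)))
    }
    pair <- mlr_pairs[[p]]
    mfit <- fit_mlr(index_table[[pair[1L]]], index_table[[pair[2L]]], y,
                    names = pair)
    entry$mlr <- c(list(index = pair),
                   fit_summary(mfit, format_equation(p, pair,
                                                     mfit$coefficients,
                                                     precision)))
    report[[p]] <- entry
  }
  structure(report, class = "qspr_report")
}

#' Write a QSPR report to CSV and JSON
#'
#' @param report a \code{\link{best_fit_report}} result.
#' @param csv,json output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the flat data frame written to CSV.
#' @export
write_qspr_report <- function(report, csv = NULL, json = NULL) {
  rows <- list()
  for (p in names(report)) {
    entry <- report[[p]]
    if (isTRUE(entry$degenerate)) next
    for (m in names(entry)) {
      e <- entry[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        property = p, model = m, index = paste(e$index, collapse = "+"),
        equation = e$equation, R = e$R, R2 = e$R2, SE = e$SE, F = e$F,
        p = e$p)
    }
  }
  flat <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(flat, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(flat)
}
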