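#' REML variance components for a multi-reader measurement study
#'
#' Fits the crossed random-effects model
#' \deqn{y_{prk} = X\beta + a_p + b_r + c_{pk} + \epsilon_{prk}}
#' by restricted maximum likelihood (via \pkg{lme4}), with patient, reader
#' and measurement occasion (the patient x replicate interaction, shared by
#' all readers of the same re-read) as random intercepts. When the table
#' contains no re-read occasions the repeat component is not identifiable; it
#' is then fixed at 0 and flagged.
#'
#' @param table Long-format data frame with columns `patient_id`, `reader_id`,
#'   `replicate`, `metric`, `side`, `value`, plus any fixed covariates.
#' @param metric,side Select the rows to analyse (default: all rows if the
#'   table holds a single metric/side).
#' @param fixed Character vector of fixed covariate columns (intersected with
#'   the available columns); default `c("age", "sex", "foi", "noise")`.
#' @param ci Logical; compute 95% profile-likelihood CIs for the variance
#'   components (slower).
#' @param ci_maxpts Profile resolution passed to [lme4::profile] when
#'   `ci = TRUE`.
#' @return Object of class `variance_components`: `constant` (fixed
#'   intercept), `var_patient`, `var_reader`, `var_repeat`, `var_residual`,
#'   `fixed_effects`, `ci` (matrix or NULL), `n_obs`, `converged`, `flags`.
#' @export
fit_variance_components <- function(table, metric = NULL, side = NULL,
                                    fixed = c("age", "sex", "foi", "noise"),
                                    ci = FALSE, ci_maxpts = 8L) {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "reader_id", "replicate", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("measurement table lacks columns: ",
                         paste(miss, collapse = ", "))
  d <- table
  if (!is.null(metric) && "metric" %in% names(d)) d <- d[d$metric == metric, ]
  if (!is.null(side) && "side" %in% names(d)) d <- d[d$side == side, ]
  if (nrow(d) == 0) stop("no rows left after metric/side selection")
  if (length(unique(d$patient_id)) < 2L || length(unique(d$reader_id)) < 2L)
    stop("need at least 2 patients and 2 readers")

  d$patient <- factor(d$patient_id)
  d$reader <- factor(d$reader_id)
  d$occasion <- interaction(d$patient, d$replicate, drop = TRUE)
  flags <- character()

  fixed <- intersect(fixed, names(d))
  drop_const <- vapply(fixed, function(f) length(unique(d[[f]])) < 2L, logical(1))
  if (any(drop_const)) {
    flags <- c(flags, paste("constant covariates dropped:",
                            paste(fixed[drop_const], collapse = ", ")))
    fixed <- fixed[!drop_const]
  }
  if (length(fixed)) {
    Xf <- stats::model.matrix(stats::reformulate(fixed), d)
    if (qr(Xf)$rank < ncol(Xf)) {
      aliased <- colnames(Xf)[-seq_len(qr(Xf)$rank)]
      stop("rank-deficient fixed-effect design; aliased: ",
           paste(aliased, collapse = ", "))
    }
  }

  has_repeats <- max(tapply(d$replicate, d$patient, function(k) length(unique(k)))) > 1L
  re_terms <- "(1 | patient) + (1 | reader)"
  if (has_repeats) re_terms <- paste(re_terms, "+ (1 | occasion)")
  else flags <- c(flags, "no re-read occasions: repeat variance fixed at 0")
  rhs <- paste(c(if (length(fixed)) fixed else "1", re_terms), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))

  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(rhobeg = 0.2, rhoend = 2e-9))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("failed to converge|boundary", conditionMessage(w))) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  conv <- fit@optinfo$conv$opt == 0
  if (!conv && length(fit@optinfo$conv$lme4))
    stop("mixed model did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))

  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  beta <- lme4::fixef(fit)

  ci_tab <- NULL
  if (ci) {
    ci_raw <- tryCatch(
      suppressWarnings(suppressMessages(
        stats::confint(fit, parm = "theta_", method = "profile",
                       oldNames = FALSE, quiet = TRUE,
                       alphamax = 0.049, maxpts = ci_maxpts))),
      error = function(e) NULL)
    if (is.null(ci_raw)) {
      flags <- c(flags, "profile CIs unavailable (profiling failed)")
    } else {
      ci_tab <- ci_raw^2   # sd scale -> variance scale
      map <- c("sd_(Intercept)|patient" = "patient",
               "sd_(Intercept)|reader" = "reader",
               "sd_(Intercept)|occasion" = "repeat",
               "sigma" = "residual")
      rownames(ci_tab) <- unname(map[rownames(ci_tab)])
    }
  }

  structure(list(constant = unname(beta["(Intercept)"]),
                 var_patient = getv("patient"),
                 var_reader = getv("reader"),
                 var_repeat = if (has_repeats) getv("occasion") else 0,
                 var_residual = vc$vcov[vc$grp == "Residual"],
                 fixed_effects = beta,
                 ci = ci_tab,
                 n_obs = nrow(d),
                 converged = conv,
                 flags = flags),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance components> n = %d obs, intercept %.2f\n",
              x$n_obs, x$constant))
  comp <- c(patient = x$var_patient, reader = x$var_reader,
            repeated = x$var_repeat, residual = x$var_residual)
  for (nm in names(comp)) cat(sprintf("  %-9s %8.3f\n", nm, comp[nm]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Repeatability and reproducibility coefficients
#'
#' The repeatability coefficient is 2.77 times the within-subject SD: 95% of
#' differences between two repeat measurements are expected to fall below it.
#' Same-reader (repeatability): `2.77 * sqrt(var_residual)`. Different-reader
#' (reproducibility): `2.77 * sqrt(var_residual + var_reader)`. Values are
#' returned at full precision; round only for presentation.
#'
#' @param vc A `variance_components` object, or the residual variance as a
#'   number.
#' @param var_reader Reader variance (ignored when `vc` is a
#'   `variance_components`).
#' @return Object of class `rc_result` with `rc_same_reader` and
#'   `rc_different_reader` (measurement units).
#' @export
repeatability_coefficients <- function(vc, var_reader = 0) {
  if (inherits(vc, "variance_components")) {
    ve <- vc$var_residual; vr <- vc$var_reader
  } else {
    ve <- as.numeric(vc); vr <- as.numeric(var_reader)
  }
  if (!is.finite(ve) || !is.finite(vr) || ve < 0 || vr < 0)
    stop("variance components must be finite and non-negative")
  structure(list(rc_same_reader = 2.77 * sqrt(ve),
                 rc_different_reader = 2.77 * sqrt(ve + vr)),
            class = "rc_result")
}

#' @export
print.rc_result <- function(x, ...) {
  cat(sprintf("RC same patient, same reader:      %.2f\n", x$rc_same_reader))
  cat(sprintf("RC same patient, different reader: %.2f\n", x$rc_different_reader))
  invisible(x)
}
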