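#' Specify a multi-reader measurement-study simulation
#'
#' Mirrors the design of a reliability study in which every reader measures
#' every patient once and a small subset of patients is re-read by all
#' readers on additional occasions (default: 5 patients read 3 times). The
#' measurement model is
#' \deqn{y_{prk} = \mu + X_p \beta + a_p + b_r + c_{pk} + \epsilon_{prk}}
#' with independent zero-mean normal patient, reader, occasion (repeat) and
#' residual components. The occasion effect \eqn{c_{pk}} is shared by all
#' readers of the same re-read, which is what makes a separate repeat
#' variance identifiable in this design.
#'
#' @param n_patients,n_readers Study size.
#' @param n_replicate_patients Number of patients re-read on extra occasions.
#' @param n_replicates Total occasions for those patients (default 3).
#' @param var_patient,var_reader,var_repeat,var_residual Variance components
#'   (squared measurement units).
#' @param mu Grand mean (measurement units).
#' @param beta Optional named fixed-effect coefficients for any of
#'   `age`, `sex`, `foi`, `noise` (default all zero).
#' @param metric,side Labels written into the output table.
#' @param seed Integer seed; all randomness flows through it.
#' @return Object of class `reader_sim_spec`.
#' @export
reader_sim_spec <- function(n_patients = 78L, n_readers = 5L,
                            n_replicate_patients = 5L, n_replicates = 3L,
                            var_patient = 39.46, var_reader = 11.88,
                            var_repeat = 7.44, var_residual = 17.80,
                            mu = 26.03, beta = NULL,
                            metric = "lcea", side = "right", seed = 1L) {
  stopifnot(n_patients >= 1, n_readers >= 1, n_replicates >= 1,
            n_replicate_patients >= 0, n_replicate_patients <= n_patients)
  vars <- c(patient = unname(var_patient), reader = unname(var_reader),
            repeat_ = unname(var_repeat), residual = unname(var_residual))
  if (any(vars < 0)) stop("variance components must be non-negative")
  b <- c(age = 0, sex = 0, foi = 0, noise = 0)
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% names(b)))
      stop("beta must be named with a subset of: age, sex, foi, noise")
    b[names(beta)] <- beta
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_readers = as.integer(n_readers),
                 n_replicate_patients = as.integer(n_replicate_patients),
                 n_replicates = as.integer(n_replicates),
                 vars = vars, mu = mu, beta = b,
                 metric = metric, side = side, seed = as.integer(seed)),
            class = "reader_sim_spec")
}

#' Simulate a multi-reader measurement study
#'
#' Generates a long-format measurement table under the crossed
#' patient x reader design of [reader_sim_spec()]. Patient covariates (age,
#' sex, FOI, noise/exposure index) are drawn once per patient and enter
#' through the fixed-effect coefficients (zero by default). Deterministic
#' given the spec seed.
#'
#' @param spec A `reader_sim_spec`.
#' @param truths Optional vector of per-patient true values (length
#'   `n_patients`). When supplied, it replaces `mu + patient effect` (the
#'   patient's latent value is taken as given, e.g. from a phantom batch);
#'   reader, occasion and residual noise are still added.
#' @return Data frame with columns `patient_id`, `reader_id`, `replicate`,
#'   `side`, `metric`, `value`, `age`, `sex`, `foi`, `noise`.
#' @export
simulate_reader_study <- function(spec, truths = NULL) {
  stopifnot(inherits(spec, "reader_sim_spec"))
  np <- spec$n_patients; nr <- spec$n_readers
  if (!is.null(truths) && length(truths) != np)
    stop("truths must have one value per patient")
  base <- expand.grid(patient_id = seq_len(np), reader_id = seq_len(nr),
                      replicate = 1L, KEEP.OUT.ATTRS = FALSE)
  if (spec$n_replicate_patients > 0 && spec$n_replicates > 1) {
    extra <- expand.grid(patient_id = seq_len(spec$n_replicate_patients),
                         reader_id = seq_len(nr),
                         replicate = 2:spec$n_replicates,
                         KEEP.OUT.ATTRS = FALSE)
    design <- rbind(base, extra)
  } else design <- base
  design <- design[order(design$patient_id, design$reader_id, design$replicate), ]
  rownames(design) <- NULL

  with_seed(spec$seed, {
    age <- stats::runif(np, 18, 91)
    sex <- stats::rbinom(np, 1, 0.5)
    foi <- stats::rnorm(np, 1, 0.05)
    noise <- stats::rnorm(np, 0, 1)
    X <- cbind(age = age, sex = sex, foi = foi, noise = noise)
    fixed <- as.vector(X %*% spec$beta)
    patient_level <- if (is.null(truths))
      spec$mu + fixed + stats::rnorm(np, 0, sqrt(spec$vars["patient"]))
    else as.numeric(truths) + fixed
    b_r <- stats::rnorm(nr, 0, sqrt(spec$vars["reader"]))
    occ_key <- unique(design[c("patient_id", "replicate")])
    occ_eff <- stats::rnorm(nrow(occ_key), 0, sqrt(spec$vars["repeat_"]))
    occ_idx <- match(paste(design$patient_id, design$replicate),
                     paste(occ_key$patient_id, occ_key$replicate))
    eps <- stats::rnorm(nrow(design), 0, sqrt(spec$vars["residual"]))
    design$side <- spec$side
    design$metric <- spec$metric
    design$value <- patient_level[design$patient_id] + b_r[design$reader_id] +
      occ_eff[occ_idx] + eps
    design$age <- age[design$patient_id]
    design$sex <- sex[design$patient_id]
    design$foi <- foi[design$patient_id]
    design$noise <- noise[design$patient_id]
  })
  design[c("patient_id", "reader_id", "replicate", "side", "metric",
           "value", "age", "sex", "foi", "noise")]
}
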