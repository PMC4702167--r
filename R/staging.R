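#' Linear regression of a feature on stage
#'
#' Ordinary least squares of a morphological feature (e.g. the log chamber
#' size) on the developmental stage, with the coefficient of determination
#' and the pointwise 95% confidence band of the predicted mean.
#'
#' @param stages numeric vector of stage labels (>= 3 distinct values).
#' @param feature numeric vector, same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `ci_band` (data
#'   frame with `stage`, `fit`, `lwr`, `upr` over a 100-point stage grid)
#'   and the underlying `lm` fit in `model`.
#' @export
fit_stage_linear <- function(stages, feature) {
  stages <- as.numeric(stages)
  feature <- as.numeric(feature)
  if (length(stages) != length(feature))
    stop("fit_stage_linear: inputs differ in length")
  if (length(unique(stages)) < 3)
    stop("fit_stage_linear: need at least 3 distinct stages")
  if (var(stages) == 0) stop("fit_stage_linear: constant stage vector")
  df <- data.frame(stage = stages, feature = feature)
  fit <- lm(feature ~ stage, data = df)
  grid <- data.frame(stage = seq(min(stages), max(stages), length.out = 100))
  band <- as.data.frame(predict(fit, grid, interval = "confidence",
                                level = 0.95))
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       ci_band = cbind(grid, band),
       model = fit)
}

ordinal_link <- function(link = c("logit", "probit")) {
  link <- match.arg(link)
  if (link == "logit") list(F = plogis, f = dlogis, name = "logit")
  else list(F = stats::pnorm, f = stats::dnorm, name = "probit")
}

ordinal_nll <- function(par, x, y, K, lk, penalty = 0) {
  beta <- par[1]
  alpha <- par[-1]
  eta_lo <- ifelse(y == 1L, Inf, beta * x - alpha[pmax(y - 1L, 1L)])
  eta_hi <- ifelse(y == K, -Inf, beta * x - alpha[pmin(y, K - 1L)])
  p <- lk$F(eta_lo) - lk$F(eta_hi)
  p <- pmax(p, 1e-12)
  -sum(log(p)) + penalty * sum(par^2)
}

ordinal_grad <- function(par, x, y, K, lk, penalty = 0) {
  beta <- par[1]
  alpha <- par[-1]
  eta_lo <- ifelse(y == 1L, Inf, beta * x - alpha[pmax(y - 1L, 1L)])
  eta_hi <- ifelse(y == K, -Inf, beta * x - alpha[pmin(y, K - 1L)])
  p <- pmax(lk$F(eta_lo) - lk$F(eta_hi), 1e-12)
  f_lo <- ifelse(is.finite(eta_lo), lk$f(eta_lo), 0)
  f_hi <- ifelse(is.finite(eta_hi), lk$f(eta_hi), 0)
  g_beta <- -sum(x * (f_lo - f_hi) / p)
  g_alpha <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    # alpha_k appears as the lower bound of class k+1 and upper bound of k
    contrib <- ifelse(y == k + 1L, f_lo, 0) - ifelse(y == k, f_hi, 0)
    g_alpha[k] <- -sum(-contrib / p)
  }
  c(g_beta, g_alpha) + 2 * penalty * par
}

#' Fit a cumulative-link ordinal regression of stage on one feature
#'
#' Proportional-odds model with `P(stage > k | x) = F(beta * x - alpha_k)`
#' (logit link by default), fitted by maximum likelihood (BFGS with
#' analytic gradient). Deterministic given data and settings. Under
#' complete separation the fit is repeated with a small ridge penalty and
#' flagged.
#'
#' @param stages vector of ordered stage labels (integers, or strings such
#'   as `"10A"`/`"10B"` which are merged into stage 10); at least 2 stages,
#'   each with at least 2 samples.
#' @param feature numeric vector, same length.
#' @param feature_name name stored in the model (default from the call).
#' @param link `"logit"` (default) or `"probit"`.
#' @return A `stage_model` object: list with `feature_name`, `coefficient`
#'   (beta), `intercepts` (alpha_k, named `"k|k+1"`), `stage_range`,
#'   `link`, `log_lik`, `converged`, `penalized` and `n`.
#' @export
fit_ordinal <- function(stages, feature,
                        feature_name = deparse(substitute(feature)),
                        link = c("logit", "probit")) {
  lk <- ordinal_link(match.arg(link))
  stages <- merge_stage_labels(stages)
  x <- as.numeric(feature)
  keep <- is.finite(x) & is.finite(stages)
  stages <- stages[keep]; x <- x[keep]
  levs <- sort(unique(stages))
  K <- length(levs)
  if (K < 2) stop("fit_ordinal: need at least 2 stages")
  if (any(table(stages) < 2))
    stop("fit_ordinal: every stage needs at least 2 samples")
  y <- match(stages, levs)
  # fit on the standardized feature for a well-conditioned optimization,
  # then transform the parameters back to the original scale
  x_m <- mean(x)
  x_s <- max(sd(x), 1e-12)
  z <- (x - x_m) / x_s
  # starting values: scaled covariance slope, boundaries between group means
  b0 <- 1.7 * cov(z, as.numeric(y)) / max(var(z), 1e-12)
  mu <- vapply(seq_len(K), function(j) mean(z[y == j]), numeric(1))
  a0 <- b0 * (mu[-K] + mu[-1]) / 2
  a0 <- cummax(a0 + seq_along(a0) * 1e-8)  # strictly ordered start
  par0 <- c(b0, a0)
  fit_once <- function(penalty) {
    optim(par0, ordinal_nll, gr = ordinal_grad, x = z, y = y, K = K, lk = lk,
          penalty = penalty, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-14))
  }
  opt <- fit_once(0)
  penalized <- FALSE
  bad <- !all(is.finite(opt$par)) || max(abs(opt$par)) > 80 ||
    is.unsorted(opt$par[-1])
  if (bad) {
    opt <- fit_once(1e-3)
    penalized <- TRUE
    warning("fit_ordinal: separation or unstable fit; ridge penalty applied")
  }
  beta <- opt$par[1] / x_s
  alpha <- opt$par[-1] + opt$par[1] * x_m / x_s
  structure(list(
    feature_name = feature_name,
    coefficient = beta,
    intercepts = setNames(alpha,
                          paste(levs[-K], levs[-1], sep = "|")),
    stage_range = levs,
    link = lk$name,
    log_lik = -opt$value,
    converged = opt$convergence == 0,
    penalized = penalized,
    n = length(x)
  ), class = "stage_model")
}

# "10A"/"10B" specimens are combined as stage 10 for model fitting; the
# centripetal-migration detector refines 10 -> 10A/10B afterwards
merge_stage_labels <- function(stages) {
  if (is.character(stages) || is.factor(stages)) {
    s <- toupper(trimws(as.character(stages)))
    s[s %in% c("10A", "10B")] <- "10"
    stages <- suppressWarnings(as.numeric(s))
    if (any(is.na(stages))) stop("unparseable stage labels")
  }
  as.numeric(stages)
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("<stage_model> %s (%s link): beta = %.4f, stages %s-%s, n = %d%s\n",
              x$feature_name, x$link, x$coefficient,
              min(x$stage_range), max(x$stage_range), x$n,
              if (isTRUE(x$penalized)) " [penalized]" else ""))
  invisible(x)
}

#' Per-stage probabilities under a fitted ordinal model
#'
#' @param object a `stage_model`.
#' @param newdata numeric vector of feature values.
#' @param ... unused.
#' @return Matrix (`length(newdata)` x stages) of class probabilities,
#'   columns named by stage; rows sum to 1.
#' @export
predict.stage_model <- function(object, newdata, ...) {
  lk <- ordinal_link(object$link)
  K <- length(object$stage_range)
  eta <- outer(object$coefficient * as.numeric(newdata), object$intercepts, `-`)
  S <- cbind(1, lk$F(eta), 0)  # survivor P(stage > k), k = 0..K
  probs <- S[, seq_len(K), drop = FALSE] - S[, seq_len(K) + 1L, drop = FALSE]
  probs <- pmax(probs, 0)
  probs <- probs / rowSums(probs)
  colnames(probs) <- object$stage_range
  probs
}

#' Feature cutoffs between consecutive stages
#'
#' The boundary between stages k and k+1 is the feature value where
#' `P(stage > k | x) = 0.5`, i.e. `alpha_k / beta`. A cutoff is reported as
#' unavailable (`NA`) when the gap between its intercept and the previous
#' one falls below `resolution_frac` times the median intercept gap,
#' mirroring stages whose feature distributions are indistinguishable.
#'
#' @param model a `stage_model` with positive coefficient.
#' @param resolution_frac fraction of the median intercept gap below which
#'   a cutoff is unavailable (default 0.1).
#' @return Named numeric vector of cutoffs (names `"k|k+1"`), `NA` where
#'   unavailable.
#' @export
stage_cutoffs <- function(model, resolution_frac = 0.1) {
  if (model$coefficient <= 0)
    stop("stage_cutoffs: coefficient <= 0; feature does not increase with stage")
  cut <- model$intercepts / model$coefficient
  gaps <- diff(model$intercepts)
  if (length(gaps)) {
    res <- resolution_frac * median(gaps)
    na_idx <- which(gaps < res) + 1L
    cut[na_idx] <- NA_real_
  }
  cut
}

#' Classify a chamber's stage from its features
#'
#' Per-stage probabilities come from the log-size model (chamber size is
#' the most stable staging feature); optionally, probabilities from other
#' feature models whose inputs are defined are fused by log-space
#' averaging.
#'
#' @param models a `stage_model` or a list of them; the model with
#'   `feature_name == "log_size"` is required.
#' @param features a `feature_vector` from [extract_features()], or a named
#'   list/vector with entries matching the models' `feature_name`s.
#' @param fuse if `TRUE`, average log-probabilities across all models with
#'   defined features (default `FALSE`: size-only classification).
#' @return A `stage_prediction` object: list with `stage` (the argmax
#'   label), `probabilities` (named, sum to 1), `cutoffs_used` (log-size
#'   cutoffs from [stage_cutoffs()]) and `models_used`.
#' @export
classify_stage <- function(models, features, fuse = FALSE) {
  if (inherits(models, "stage_model")) models <- list(models)
  names(models) <- vapply(models, `[[`, character(1), "feature_name")
  if (!"log_size" %in% names(models))
    stop("classify_stage: a log_size model is required")
  feat_val <- function(nm) {
    v <- features[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  base <- models[["log_size"]]
  use <- if (fuse) {
    ok <- vapply(names(models), function(nm) is.finite(feat_val(nm)), logical(1))
    names(models)[ok]
  } else "log_size"
  if (!"log_size" %in% use) stop("classify_stage: log_size feature missing")
  logp <- 0
  for (nm in use) {
    p <- predict(models[[nm]], feat_val(nm))[1, ]
    logp <- logp + log(pmax(p, 1e-300))
  }
  logp <- logp / length(use)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  cuts <- tryCatch(stage_cutoffs(base), error = function(e) NULL)
  structure(list(stage = base$stage_range[which.max(p)],
                 probabilities = setNames(p, base$stage_range),
                 cutoffs_used = cuts,
                 models_used = use),
            class = "stage_prediction")
}

#' @export
print.stage_prediction <- function(x, ...) {
  cat(sprintf("<stage_prediction> stage %s (p = %.3f; models: %s)\n",
              x$stage, max(x$probabilities),
              paste(x$models_used, collapse = ", ")))
  invisible(x)
}

#' Two-sample t-test
#'
#' Standard two-sample t-test with pooled variance by default (Welch as an
#' option), two-sided.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param var_equal pooled-variance Student test if `TRUE` (default),
#'   Welch otherwise.
#' @return A list with `t`, `df` and `p`.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("two_sample_ttest: each group needs at least 2 values")
  if (var_equal && var(group_a) + var(group_b) == 0)
    stop("two_sample_ttest: zero pooled variance")
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Two-Gaussian intersection cutoff (stage 8 vs stage 9 rule)
#'
#' Fits a Gaussian to each group's Delta-distances (sample mean and SD) and
#' returns the intersection of the two density curves between the means as
#' the classification cutoff; a chamber with Delta-distance above the
#' cutoff is called the higher-Delta group (stage 9). When the SDs are
#' equal the unique intersection is the midpoint of the means. A two-sample
#' t-test of the group difference is included.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each, positive SDs).
#' @param var_equal passed to [two_sample_ttest()].
#' @return A `gaussian_cutoff` object: list with `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `cutoff`, `between_means` (`FALSE` flags the
#'   pathological no-root case, where the midpoint is used as fallback),
#'   `t_statistic`, `df` and `p_value`.
#' @export
#' @examples
#' gaussian_intercept_rule(rnorm(20, 0.12, 0.05), rnorm(20, 0.30, 0.05))
gaussian_intercept_rule <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("gaussian_intercept_rule: each group needs at least 2 values")
  ma <- mean(group_a); sa <- sd(group_a)
  mb <- mean(group_b); sb <- sd(group_b)
  if (sa <= 0 || sb <= 0)
    stop("gaussian_intercept_rule: positive sample SDs required")
  lo <- min(ma, mb); hi <- max(ma, mb)
  between <- TRUE
  if (abs(sa - sb) < 1e-12 * max(sa, sb)) {
    cutoff <- (ma + mb) / 2
  } else {
    # equate log densities: quadratic A x^2 + B x + C = 0
    A <- 1 / sa^2 - 1 / sb^2
    B <- -2 * (ma / sa^2 - mb / sb^2)
    C <- ma^2 / sa^2 - mb^2 / sb^2 + 2 * log(sa / sb)
    disc <- B^2 - 4 * A * C
    roots <- if (disc < 0) numeric(0)
             else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    roots <- roots[roots >= lo & roots <= hi]
    if (length(roots)) {
      cutoff <- roots[1]
    } else {
      between <- FALSE
      cutoff <- (ma + mb) / 2
      warning("gaussian_intercept_rule: no density intersection between ",
              "the means; midpoint fallback used")
    }
  }
  tt <- two_sample_ttest(group_a, group_b, var_equal = var_equal)
  structure(list(mean_a = ma, sd_a = sa, mean_b = mb, sd_b = sb,
                 cutoff = cutoff, between_means = between,
                 t_statistic = tt$t, df = tt$df, p_value = tt$p),
            class = "gaussian_cutoff")
}

#' @export
print.gaussian_cutoff <- function(x, ...) {
  cat(sprintf(paste0("<gaussian_cutoff> cutoff %.4f ",
                     "(means %.4f / %.4f; t = %.2f, p = %.3g)\n"),
              x$cutoff, x$mean_a, x$mean_b, x$t_statistic, x$p_value))
  invisible(x)
}

#' Train the per-feature ordinal staging models from a feature table
#'
#' @param table a data frame (or path to a CSV file) with columns `stage`,
#'   `area_um2` (or `log_size`), and optionally `oocyte_fraction`,
#'   `chamber_ratio`.
#' @param link passed to [fit_ordinal()].
#' @return Named list of `stage_model`s (`log_size` always present;
#'   `oocyte_fraction` and `chamber_ratio` when the columns exist with
#'   enough defined values).
#' @export
train_stage_models <- function(table, link = "logit") {
  if (is.character(table)) table <- utils::read.csv(table)
  stages <- table$stage
  if (is.null(stages)) stop("train_stage_models: no `stage` column")
  log_size <- if (!is.null(table$log_size)) table$log_size
              else if (!is.null(table$area_um2)) log(table$area_um2)
              else stop("train_stage_models: need `log_size` or `area_um2`")
  models <- list(log_size = fit_ordinal(stages, log_size,
                                        feature_name = "log_size",
                                        link = link))
  for (nm in c("oocyte_fraction", "chamber_ratio")) {
    v <- table[[nm]]
    if (is.null(v)) next
    ok <- is.finite(v)
    st <- merge_stage_labels(stages)[ok]
    if (length(unique(st)) >= 2 && all(table(st) >= 2)) {
      models[[nm] ] <- tryCatch(
        fit_ordinal(st, v[ok], feature_name = nm, link = link),
        error = function(e) NULL)
    }
  }
  models[!vapply(models, is.null, logical(1))]
}

#' Save / load staging models as JSON
#'
#' @param models a `stage_model` or named list of them.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; the model list for the reader.
#' @export
write_stage_models <- function(models, path) {
  if (inherits(models, "stage_model")) models <- list(models)
  out <- lapply(models, function(m)
    list(feature_name = m$feature_name, coefficient = m$coefficient,
         intercepts = as.list(m$intercepts), stage_range = m$stage_range,
         link = m$link, n = m$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stage_models
#' @export
read_stage_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    structure(list(
      feature_name = m$feature_name,
      coefficient = as.numeric(m$coefficient),
      intercepts = setNames(as.numeric(unlist(m$intercepts)),
                            names(m$intercepts)),
      stage_range = as.numeric(unlist(m$stage_range)),
      link = m$link,
      log_lik = NA_real_, converged = NA, penalized = NA,
      n = as.integer(m$n)
    ), class = "stage_model")
  })
}
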