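validate_long_study <- function(data) {
  need <- c("patient_id", "timepoint", "fd_mean")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data[c("patient_id", "timepoint")])) {
    stop("each (patient_id, timepoint) may appear at most once", call. = FALSE)
  }
  nt <- table(data$patient_id)
  if (any(nt < 2)) {
    stop(
      "every patient needs at least two timepoints; offending: ",
      paste(names(nt)[nt < 2], collapse = ", "),
      call. = FALSE
    )
  }
  if (length(unique(data$timepoint)) < 2) {
    stop("need at least two distinct timepoints to model change over time", call. = FALSE)
  }
  invisible(data)
}

wald_test <- function(b, V, idx) {
  bi <- b[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- drop(t(bi) %*% solve(Vi, bi))
  tibble::tibble(
    wald_chi2 = stat, df = length(idx),
    p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE)
  )
}

# Gaussian identity-link GEE with exchangeable working correlation and a
# robust (sandwich) covariance; clusters are patients.
gee_exchangeable <- function(X, y, id, max_iter = 50, tol = 1e-10) {
  p <- ncol(X)
  groups <- split(seq_along(y), id)
  beta <- stats::lm.fit(X, y)$coefficients
  alpha <- 0
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    sigma2 <- sum(r^2) / (length(y) - p)
    num <- 0
    npairs <- 0
    for (g in groups) {
      if (length(g) < 2) next
      rg <- r[g]
      num <- num + (sum(rg)^2 - sum(rg^2)) / 2
      npairs <- npairs + length(g) * (length(g) - 1) / 2
    }
    alpha_new <- num / ((npairs - p) * sigma2)
    alpha_new <- min(max(alpha_new, -0.99), 0.99)
    A <- matrix(0, p, p)
    u <- numeric(p)
    for (g in groups) {
      n_i <- length(g)
      Xi <- X[g, , drop = FALSE]
      # (1-a)I + aJ inverse via Sherman-Morrison
      c1 <- 1 / (1 - alpha_new)
      c2 <- -alpha_new / ((1 - alpha_new) * (1 + (n_i - 1) * alpha_new))
      XtRi <- c1 * t(Xi) + c2 * tcrossprod(colSums(Xi), rep(1, n_i))
      A <- A + XtRi %*% Xi
      u <- u + drop(XtRi %*% y[g])
    }
    beta_new <- solve(A, u)
    done <- max(abs(beta_new - beta)) < tol && abs(alpha_new - alpha) < tol
    beta <- beta_new
    alpha <- alpha_new
    if (done) break
  }
  # sandwich
  r <- y - drop(X %*% beta)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (g in groups) {
    n_i <- length(g)
    Xi <- X[g, , drop = FALSE]
    c1 <- 1 / (1 - alpha)
    c2 <- -alpha / ((1 - alpha) * (1 + (n_i - 1) * alpha))
    XtRi <- c1 * t(Xi) + c2 * tcrossprod(colSums(Xi), rep(1, n_i))
    A <- A + XtRi %*% Xi
    s <- drop(XtRi %*% r[g])
    B <- B + tcrossprod(s)
  }
  Ainv <- solve(A)
  list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = Ainv %*% B %*% Ainv, alpha = alpha, iterations = it,
    converged = it < max_iter
  )
}

#' Longitudinal model for fractal-dimension records
#'
#' Fits per-visit mean FD on the chosen fixed effects with a per-patient
#' random intercept, the standard approach for an unbalanced panel in which
#' not every patient attends every visit. Time enters as a categorical
#' factor (months 0/3/6/12, baseline reference), so each time coefficient is
#' directly the baseline contrast; age enters continuous. Two estimation
#' routes are available: a linear mixed model (lme4, REML; the default) and a
#' generalized estimating equation with exchangeable working correlation and
#' robust sandwich covariance, whose output is the classical "Wald chi-square"
#' presentation. Both report, per fixed effect, a joint Wald chi-square test,
#' and -- when `time` is included -- the pairwise baseline contrasts
#' (0 vs 3, 0 vs 6, 0 vs 12) with unadjusted and Holm-adjusted p-values.
#'
#' @param data Tibble of FD records: `patient_id`, `timepoint`, `fd_mean`,
#'   plus any of `jaw`, `sex`, `age` used as fixed effects. Every patient
#'   must contribute at least two timepoints.
#' @param fixed_effects Subset of `c("time", "jaw", "sex", "age")`.
#' @param method `"lmm"` (random-intercept linear mixed model) or `"gee"`.
#' @return An object of class `fd_longfit` with elements `contrasts` (tibble:
#'   `label`, `estimate`, `se`, `wald_chi2`, `df`, `p_value`, `p_holm`),
#'   `effects` (joint Wald tests per fixed effect), `coefficients`, `vcov`,
#'   `model`, `method`, `n`, `n_patients`, `converged`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
#' @examples
#' d <- simulate_fd_panel(time_effects = c("12" = 0.08), seed = 3)
#' fit <- fit_longitudinal(d)
#' fit$contrasts
fit_longitudinal <- function(data, fixed_effects = c("time", "jaw"),
                             method = c("lmm", "gee")) {
  method <- match.arg(method)
  bad <- setdiff(fixed_effects, c("time", "jaw", "sex", "age"))
  if (length(bad)) stop("unknown fixed effects: ", paste(bad, collapse = ", "), call. = FALSE)
  validate_long_study(data)
  d <- tibble::as_tibble(data)
  d$time <- factor(d$timepoint, levels = sort(unique(d$timepoint)))
  if ("jaw" %in% fixed_effects) d$jaw <- factor(d$jaw, levels = c("maxilla", "mandible"))
  if ("sex" %in% fixed_effects) d$sex <- factor(d$sex, levels = c("female", "male"))
  rhs <- paste(fixed_effects, collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  term_assign <- attr(X, "assign")
  term_labels <- c("(Intercept)", attr(stats::terms(stats::as.formula(paste("~", rhs))), "term.labels"))

  if (method == "lmm") {
    fml <- stats::as.formula(paste("fd_mean ~", rhs, "+ (1 | patient_id)"))
    model <- lme4::lmer(fml, data = d, REML = TRUE)
    b <- lme4::fixef(model)
    V <- as.matrix(stats::vcov(model))
    msgs <- unlist(model@optinfo$conv$lme4$messages)
    # a boundary (singular) fit is a converged model with a zero variance
    # component, common under null simulations; only real failures count
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    converged <- length(msgs) == 0
    diag_msg <- msgs
  } else {
    g <- gee_exchangeable(X, d$fd_mean, d$patient_id)
    model <- g
    b <- g$coefficients
    V <- g$vcov
    converged <- g$converged
    diag_msg <- if (converged) NULL else "GEE did not converge"
  }
  if (!converged) {
    warning(
      "model did not converge cleanly: ",
      paste(diag_msg, collapse = "; "),
      call. = FALSE
    )
  }

  effects <- purrr::map_dfr(setdiff(unique(term_assign), 0), function(a) {
    idx <- which(term_assign == a)
    dplyr::bind_cols(tibble::tibble(effect = term_labels[a + 1]), wald_test(b, V, idx))
  })

  contrasts <- NULL
  if ("time" %in% fixed_effects) {
    lev <- levels(d$time)
    cn <- paste0("time", lev[-1])
    idx <- match(cn, names(b))
    contrasts <- purrr::map_dfr(seq_along(cn), function(i) {
      est <- b[idx[i]]
      se <- sqrt(V[idx[i], idx[i]])
      tibble::tibble(
        label = sprintf("month %s vs month %s", lev[1], lev[i + 1]),
        estimate = unname(est), se = unname(se),
        wald_chi2 = unname((est / se)^2), df = 1,
        p_value = stats::pchisq((est / se)^2, 1, lower.tail = FALSE)
      )
    })
    contrasts$p_holm <- stats::p.adjust(contrasts$p_value, "holm")
  }

  structure(
    list(
      method = method, model = model,
      coefficients = tibble::tibble(
        term = names(b), estimate = unname(b),
        se = sqrt(diag(V))
      ),
      vcov = V, effects = effects, contrasts = contrasts,
      n = nrow(d), n_patients = length(unique(d$patient_id)),
      fixed_effects = fixed_effects, converged = converged
    ),
    class = "fd_longfit"
  )
}

#' @export
print.fd_longfit <- function(x, ...) {
  cat(sprintf(
    "<fd_longfit> %s fit: %d visits, %d patients; fixed effects: %s\n",
    toupper(x$method), x$n, x$n_patients, paste(x$fixed_effects, collapse = ", ")
  ))
  cat("Joint Wald tests:\n")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("Baseline time contrasts:\n")
    print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Tidy a longitudinal FD fit
#'
#' @param x An `fd_longfit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect coefficients with `term`, `estimate`, `se`,
#'   `statistic` (Wald chi-square, 1 df) and `p.value`.
#' @method tidy fd_longfit
#' @export
tidy.fd_longfit <- function(x, ...) {
  dplyr::mutate(x$coefficients,
    statistic = (.data$estimate / .data$se)^2,
    p.value = stats::pchisq(.data$statistic, 1, lower.tail = FALSE)
  )
}

#' One-row summary of a longitudinal FD fit
#'
#' @param x An `fd_longfit`.
#' @param ... Unused.
#' @return Tibble with `method`, `n`, `n_patients`, `converged` and (LMM)
#'   variance components or (GEE) working correlation.
#' @method glance fd_longfit
#' @export
glance.fd_longfit <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method, n = x$n, n_patients = x$n_patients,
    converged = x$converged
  )
  if (x$method == "lmm") {
    vc <- as.data.frame(lme4::VarCorr(x$model))
    out$sd_patient <- vc$sdcor[vc$grp == "patient_id"]
    out$sd_resid <- vc$sdcor[vc$grp == "Residual"]
  } else {
    out$working_alpha <- x$model$alpha
  }
  out
}

#' Forest plot of baseline time contrasts
#'
#' @param object An `fd_longfit` fitted with a time effect.
#' @param ... Unused.
#' @return A ggplot of contrast estimates with 95% Wald intervals.
#' @method autoplot fd_longfit
#' @export
autoplot.fd_longfit <- function(object, ...) {
  if (is.null(object$contrasts)) {
    stop("fit has no time contrasts to plot", call. = FALSE)
  }
  d <- object$contrasts
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$estimate - 1.96 * .data$se,
        xmax = .data$estimate + 1.96 * .data$se
      ),
      height = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "FD change vs baseline", y = NULL) +
    ggplot2::theme_minimal()
}

#' Two-sided t-test between independent groups
#'
#' Welch's unequal-variance t-test by default (Student's pooled test via
#' `var_equal = TRUE`), used e.g. to compare FD between sexes. Two identical
#' constant groups are reported as `t = 0, p = 1` rather than erroring.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param var_equal Assume equal variances (Student) instead of Welch.
#' @return One-row tibble: `estimate` (mean of `x` minus mean of `y`),
#'   `statistic`, `df`, `p_value`, `conf_low`, `conf_high`, `method`.
#' @export
two_group_test <- function(x, y, var_equal = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("groups must be finite and free of missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(
        estimate = 0, statistic = 0, df = length(x) + length(y) - 2,
        p_value = 1, conf_low = 0, conf_high = 0,
        method = if (var_equal) "Student t" else "Welch t"
      ))
    }
    stop("both groups are constant with different means: t is unbounded", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
    method = if (var_equal) "Student t" else "Welch t"
  )
}

#' Descriptive FD table by sex, time and jaw
#'
#' N / mean / SD / min / max of per-visit mean FD within each level of sex,
#' time and jaw, plus the overall total -- the classical one-table cohort
#' description. SD uses the n-1 denominator; for a single record it is
#' reported as 0 with `sd_undefined = TRUE`.
#'
#' @param data FD record tibble with `fd_mean`, `sex`, `timepoint`, `jaw`.
#' @return A tibble with columns `factor`, `level`, `n`, `mean`, `sd`, `min`,
#'   `max`, `sd_undefined`.
#' @export
summarize_study <- function(data) {
  stopifnot(nrow(data) > 0, "fd_mean" %in% names(data))
  d <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$fd_mean))
  one <- function(sub, factor, level) {
    tibble::tibble(
      factor = factor, level = level, n = nrow(sub),
      mean = mean(sub$fd_mean),
      sd = if (nrow(sub) > 1) stats::sd(sub$fd_mean) else 0,
      min = min(sub$fd_mean), max = max(sub$fd_mean),
      sd_undefined = nrow(sub) < 2
    )
  }
  block <- function(var) {
    lv <- sort(unique(as.character(d[[var]])))
    purrr::map_dfr(lv, function(l) one(d[as.character(d[[var]]) == l, ], var, l))
  }
  vars <- intersect(c("sex", "timepoint", "jaw"), names(d))
  dplyr::bind_rows(
    purrr::map_dfr(vars, block),
    one(d, "total", "Total")
  )
}

#' Spaghetti plot of FD trajectories
#'
#' @param data FD record tibble (`patient_id`, `timepoint`, `fd_mean`, and
#'   optionally `jaw` for colouring).
#' @return A ggplot of per-patient FD over follow-up time.
#' @export
plot_fd_trajectories <- function(data) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$timepoint, y = .data$fd_mean, group = .data$patient_id)
  )
  if ("jaw" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$jaw), alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.4)
  }
  p +
    ggplot2::stat_summary(
      ggplot2::aes(group = 1),
      fun = mean, geom = "line", linewidth = 1.2, colour = "black"
    ) +
    ggplot2::scale_x_continuous(breaks = c(0, 3, 6, 12)) +
    ggplot2::labs(x = "months after implant placement", y = "fractal dimension") +
    ggplot2::theme_minimal()
}
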