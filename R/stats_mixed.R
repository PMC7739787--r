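#' Log-transform a response when it is clearly non-normal
#'
#' Decision rule: a Shapiro-Wilk test at alpha = 0.01 on the values (capped
#' at n = 500 by a reproducible seeded subsample). If normality is rejected,
#' all values are positive, and the log scale is no worse (larger Shapiro
#' p), the log transform is applied. Non-positive non-normal values fall
#' back to no transform with a warning. Constant input is flagged degenerate
#' and left untouched.
#'
#' @param values numeric vector.
#' @param alpha rejection level for the normality test.
#' @param groups optional factor; when given, the normality test runs on
#'   within-cell residuals (values minus cell means) so that genuine group
#'   effects are not mistaken for non-normality. [fit_mixed()] passes the
#'   crossed fixed factors here.
#' @return List: `values` (possibly transformed), `transform` (`"none"` or
#'   `"log"`), `p_raw`, `p_log` (NA when not evaluated), `degenerate`.
#' @export
maybe_log_transform <- function(values, alpha = 0.01, groups = NULL) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 3 || stats::sd(v) == 0)
    return(list(values = values, transform = "none", p_raw = NA_real_,
                p_log = NA_real_, degenerate = TRUE))
  testable <- function(x) {
    r <- if (is.null(groups)) x - mean(x)
    else x - stats::ave(x, groups[is.finite(values)])
    if (length(r) > 500) r[with_seed(1L, sample.int(length(r), 500))] else r
  }
  p_raw <- stats::shapiro.test(testable(v))$p.value
  p_log <- NA_real_
  transform <- "none"
  if (p_raw < alpha) {
    if (all(v > 0)) {
      p_log <- stats::shapiro.test(testable(log(v)))$p.value
      if (p_log > p_raw) transform <- "log"
    } else {
      warning("response non-normal but not positive; log transform skipped")
    }
  }
  list(values = if (transform == "log") log(values) else values,
       transform = transform, p_raw = p_raw, p_log = p_log,
       degenerate = FALSE)
}

# ---- closed-form REML pieces for a random-intercept model --------------
# V_j = sigma2 I + tau2 J per group; inverse and determinant in closed form.
reml_env <- function(X, y, group) {
  gs <- split(seq_along(y), group)
  list(X = X, y = y, gs = gs,
       A = lapply(gs, function(i) crossprod(X[i, , drop = FALSE])),
       u = lapply(gs, function(i) colSums(X[i, , drop = FALSE])),
       b = lapply(gs, function(i) crossprod(X[i, , drop = FALSE], y[i])),
       s = vapply(gs, function(i) sum(y[i]), numeric(1)),
       yy = vapply(gs, function(i) sum(y[i]^2), numeric(1)),
       nj = lengths(gs), n = length(y), p = ncol(X))
}

reml_parts <- function(env, tau2, sigma2) {
  w <- tau2 / (sigma2 + env$nj * tau2)
  M <- 0; Xty <- 0; yVy <- 0
  for (j in seq_along(env$gs)) {
    M <- M + (env$A[[j]] - w[j] * tcrossprod(env$u[[j]]))
    Xty <- Xty + (env$b[[j]] - w[j] * env$u[[j]] * env$s[j])
    yVy <- yVy + (env$yy[j] - w[j] * env$s[j]^2)
  }
  list(M = M / sigma2, Xty = Xty / sigma2, yVy = yVy / sigma2)
}

reml_m2ll <- function(env, tau2, sigma2) {
  parts <- reml_parts(env, tau2, sigma2)
  logdetV <- sum((env$nj - 1) * log(sigma2) + log(sigma2 + env$nj * tau2))
  beta <- solve(parts$M, parts$Xty)
  quad <- parts$yVy - sum(beta * parts$Xty)
  as.numeric(logdetV + determinant(parts$M, logarithm = TRUE)$modulus + quad)
}

vcov_beta_at <- function(env, tau2, sigma2) solve(reml_parts(env, tau2, sigma2)$M)

# 2x2 covariance of (tau2, sigma2) from the REML Hessian; NULL on boundary.
varpar_cov <- function(env, tau2, sigma2) {
  if (tau2 < 1e-10 * sigma2) return(NULL)
  th <- c(tau2, sigma2)
  h <- pmax(1e-4 * th, 1e-10)
  f <- function(t) reml_m2ll(env, max(t[1], 0), max(t[2], 1e-12))
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (k in i:2) {
    ei <- ek <- c(0, 0); ei[i] <- h[i]; ek[k] <- h[k]
    H[i, k] <- H[k, i] <-
      (f(th + ei + ek) - f(th + ei - ek) - f(th - ei + ek) + f(th - ei - ek)) /
      (4 * h[i] * h[k])
  }
  out <- try(2 * solve(H), silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

# Satterthwaite denominator df for the contrast c'beta.
satt_df <- function(env, tau2, sigma2, cvec, cov_vp) {
  resid_df <- env$n - env$p
  g0 <- as.numeric(crossprod(cvec, vcov_beta_at(env, tau2, sigma2) %*% cvec))
  if (is.null(cov_vp)) return(resid_df)
  th <- c(tau2, sigma2)
  h <- pmax(1e-4 * th, 1e-10)
  grad <- numeric(2)
  for (i in 1:2) {
    e <- c(0, 0); e[i] <- h[i]
    gp <- as.numeric(crossprod(cvec, vcov_beta_at(env, max(th[1] + e[1], 0),
                                                  th[2] + e[2]) %*% cvec))
    gm <- as.numeric(crossprod(cvec, vcov_beta_at(env, max(th[1] - e[1], 0),
                                                  th[2] - e[2]) %*% cvec))
    grad[i] <- (gp - gm) / (2 * h[i])
  }
  denom <- as.numeric(crossprod(grad, cov_vp %*% grad))
  if (denom <= 0) return(resid_df)
  min(max(2 * g0^2 / denom, 1), resid_df)
}

#' Fit the study's mixed linear model to a metrics table
#'
#' Fits `response ~ discipline * leg + (1 | id)` (or any fixed-factor
#' formula you pass, e.g. `~ discipline` for the angle extrema, which are
#' taken from one leg only) by REML with a random intercept on the
#' skier-session, using \pkg{lme4}. The repeated cycles within a session are
#' what breaks observation independence; the random intercept absorbs that
#' autocorrelation and tolerates unbalanced designs.
#'
#' The returned object carries Type-III-style F tests for each fixed term,
#' built from marginal-mean contrasts with Satterthwaite denominator degrees
#' of freedom computed from the closed-form REML surface of the
#' random-intercept model.
#'
#' @param data metrics data frame; fixed-effect variables must be factors
#'   (characters are converted, with `discipline` ordered SL, GS, SG, DH and
#'   `leg` ordered IL, OL).
#' @param response name of the response column.
#' @param fixed one-sided formula of fixed effects, default
#'   `~ discipline * leg`.
#' @param group name of the random-intercept grouping column, default
#'   `"id"`.
#' @param transform `"auto"` (apply [maybe_log_transform()]), `"none"` or
#'   `"log"`.
#' @param tests compute the ANOVA table (default `TRUE`); disable in tight
#'   simulation loops that only need contrasts.
#' @return Object of class `ski_mixed`: the lme4 fit, variance components
#'   `tau2` (session) and `sigma2` (residual), the `anova` table (term, F,
#'   ndf, ddf, p), the transform used, and internals for contrast methods.
#' @export
fit_mixed <- function(data, response, fixed = ~ discipline * leg,
                      group = "id", transform = c("auto", "none", "log"),
                      tests = TRUE) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(data), group %in% names(data))
  vars <- all.vars(fixed)
  for (v in vars) {
    if (!is.factor(data[[v]])) {
      lev <- switch(v, discipline = c("SL", "GS", "SG", "DH"),
                    leg = c("IL", "OL"), unique(data[[v]]))
      data[[v]] <- factor(data[[v]], levels = intersect(lev, unique(data[[v]])))
    }
    if (nlevels(data[[v]]) < 2) stop("fixed factor `", v, "` needs >= 2 levels")
  }
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 3) stop("need >= 3 grouping levels")
  keep <- stats::complete.cases(data[, c(response, group, vars)])
  data <- droplevels(data[keep, , drop = FALSE])
  y <- data[[response]]
  tr <- switch(transform,
               auto = maybe_log_transform(y, groups = interaction(data[vars])),
               none = list(values = y, transform = "none"),
               log = {
                 if (any(y <= 0, na.rm = TRUE)) stop("log transform needs positive values")
                 list(values = log(y), transform = "log")
               })
  data$.y <- tr$values
  fml <- stats::as.formula(paste(".y ~", paste(deparse(fixed[[2]]), collapse = ""),
                                 "+ (1 |", group, ")"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == group]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  beta <- lme4::fixef(fit)
  X <- lme4::getME(fit, "X")
  env <- reml_env(X, data$.y, data[[group]])
  cov_vp <- varpar_cov(env, tau2, sigma2)
  obj <- structure(list(fit = fit, data = data, response = response,
                        transform = tr$transform, fixed = fixed,
                        factors = vars, group = group, beta = beta,
                        vcov_beta = vcov_beta_at(env, tau2, sigma2),
                        tau2 = tau2, sigma2 = sigma2, env = env,
                        cov_vp = cov_vp, messages = msgs),
                   class = "ski_mixed")
  if (tests) obj$anova <- anova_table(obj)
  obj
}

# model-matrix rows for every cell of the fixed-factor grid
cell_grid <- function(object) {
  lev <- lapply(object$factors, function(v) levels(object$data[[v]]))
  names(lev) <- object$factors
  grid <- expand.grid(lev, stringsAsFactors = FALSE)
  tt <- stats::delete.response(stats::terms(stats::as.formula(
    paste("~", paste(deparse(object$fixed[[2]]), collapse = "")))))
  for (v in object$factors) grid[[v]] <- factor(grid[[v]], levels = lev[[v]])
  Xg <- stats::model.matrix(tt, grid)
  list(grid = grid, X = Xg)
}

# marginal-mean rows for one factor (averaging over the others)
marginal_rows <- function(object, factor_name, cg = cell_grid(object)) {
  lev <- levels(object$data[[factor_name]])
  t(vapply(lev, function(l) {
    colMeans(cg$X[cg$grid[[factor_name]] == l, , drop = FALSE])
  }, numeric(ncol(cg$X))))
}

wald_F <- function(object, L) {
  L <- matrix(L, ncol = length(object$beta))
  q <- qr(L)$rank
  A <- L %*% object$vcov_beta %*% t(L)
  est <- L %*% object$beta
  Fval <- as.numeric(crossprod(est, solve(A, est))) / q
  # Satterthwaite ddf via eigen-contrasts (averaged as 2E/(E - q))
  ev <- eigen(A, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  P <- ev$vectors[, keep, drop = FALSE]
  dfs <- apply(t(P) %*% L, 1, function(cv)
    satt_df(object$env, object$tau2, object$sigma2, cv, object$cov_vp))
  dfs2 <- dfs[dfs > 2]
  E <- sum(dfs2 / (dfs2 - 2))
  ddf <- if (length(dfs2) == length(dfs) && E > q) 2 * E / (E - q)
         else object$env$n - object$env$p
  c(F = Fval, ndf = q, ddf = ddf,
    p = stats::pf(Fval, q, ddf, lower.tail = FALSE))
}

anova_table <- function(object) {
  cg <- cell_grid(object)
  terms_ <- attr(stats::terms(object$fixed), "term.labels")
  rows <- lapply(terms_, function(tm) {
    fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(fs) == 1) {
      M <- marginal_rows(object, fs, cg)
      L <- sweep(M, 2, colMeans(M))[-1, , drop = FALSE]
    } else {
      # double differences of cell means (full-rank interaction contrasts)
      f1 <- fs[1]; f2 <- fs[2]
      l1 <- levels(object$data[[f1]]); l2 <- levels(object$data[[f2]])
      cell <- function(a, b)
        colMeans(cg$X[cg$grid[[f1]] == a & cg$grid[[f2]] == b, , drop = FALSE])
      L <- do.call(rbind, unlist(lapply(l1[-1], function(a) {
        lapply(l2[-1], function(b) {
          cell(a, b) - cell(a, l2[1]) - cell(l1[1], b) + cell(l1[1], l2[1])
        })
      }), recursive = FALSE))
    }
    wald_F(object, L)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$term <- terms_
  out[, c("term", "F", "ndf", "ddf", "p")]
}

#' @export
print.ski_mixed <- function(x, ...) {
  cat(sprintf("<ski_mixed> %s (transform: %s) | tau2 = %.4g, sigma2 = %.4g\n",
              x$response, x$transform, x$tau2, x$sigma2))
  if (!is.null(x$anova)) print(x$anova, row.names = FALSE, digits = 4)
  if (length(x$messages))
    cat("fitting messages:", paste(unique(x$messages), collapse = "; "), "\n")
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' All pairwise differences of estimated marginal means of `factor`,
#' optionally within each level of `by` (a separate Tukey family per slice,
#' mirroring per-leg discipline comparisons and per-discipline leg
#' comparisons). The adjusted p uses the studentized range distribution with
#' the family size k and Satterthwaite df of each contrast; with k = 2 it
#' reduces to the unadjusted t-test p. Each contrast also carries the
#' mixed-model Cohen's d (see [cohens_d_mixed()]) and its label.
#'
#' @param object a `ski_mixed` fit.
#' @param factor name of the fixed factor to compare.
#' @param by optional name of a second factor defining slices.
#' @return Data frame: `family`, `contrast`, `estimate`, `se`, `df`, `t`,
#'   `p_adj`, `cohens_d`, `effect`.
#' @export
tukey_contrasts <- function(object, factor = "discipline", by = NULL) {
  stopifnot(inherits(object, "ski_mixed"), factor %in% object$factors)
  if (nlevels(object$data[[factor]]) < 2) stop("factor has a single level")
  cg <- cell_grid(object)
  slices <- if (is.null(by)) list(`.` = rep(TRUE, nrow(cg$grid)))
  else {
    stopifnot(by %in% object$factors)
    stats::setNames(lapply(levels(object$data[[by]]),
                           function(l) cg$grid[[by]] == l),
                    levels(object$data[[by]]))
  }
  sd_total <- sqrt(object$tau2 + object$sigma2)
  out <- list()
  for (sl in names(slices)) {
    sel <- slices[[sl]]
    lev <- levels(object$data[[factor]])
    rows <- t(vapply(lev, function(l) {
      colMeans(cg$X[sel & cg$grid[[factor]] == l, , drop = FALSE])
    }, numeric(ncol(cg$X))))
    k <- length(lev)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cvec <- rows[i, ] - rows[j, ]
      est <- sum(cvec * object$beta)
      se <- sqrt(as.numeric(crossprod(cvec, object$vcov_beta %*% cvec)))
      df <- satt_df(object$env, object$tau2, object$sigma2, cvec, object$cov_vp)
      tstat <- est / se
      p <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df,
                         lower.tail = FALSE)
      d <- cohens_d_mixed(est, object$tau2, object$sigma2)
      out[[length(out) + 1]] <- data.frame(
        family = if (is.null(by)) factor else paste0(factor, " | ", by, "=", sl),
        contrast = paste(lev[i], "-", lev[j]), estimate = est, se = se,
        df = df, t = tstat, p_adj = p, cohens_d = d,
        effect = classify_effect(d), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Estimated marginal means
#'
#' @param object a `ski_mixed` fit.
#' @param factors factor names defining the grid (default: all fixed
#'   factors, i.e. the cell means).
#' @return Data frame of levels, `emmean` and `se` (model scale).
#' @export
estimated_marginal_means <- function(object, factors = object$factors) {
  cg <- cell_grid(object)
  keyed <- interaction(cg$grid[factors], drop = TRUE, lex.order = TRUE)
  rows <- t(vapply(levels(keyed), function(l) {
    colMeans(cg$X[keyed == l, , drop = FALSE])
  }, numeric(ncol(cg$X))))
  grid <- unique(cg$grid[factors])
  grid <- grid[order(interaction(grid, drop = TRUE, lex.order = TRUE)), ,
               drop = FALSE]
  grid$emmean <- as.numeric(rows %*% object$beta)
  grid$se <- sqrt(rowSums((rows %*% object$vcov_beta) * rows))
  rownames(grid) <- NULL
  grid
}

#' Cohen's d for a mixed-model contrast
#'
#' Standardizes a marginal-mean difference by the total random SD,
#' `sqrt(tau2 + sigma2)` — the sum of all variance components — which is the
#' standardizer appropriate for mixed designs (a subject-level SD, not the
#' residual alone).
#'
#' @param estimate contrast estimate (model scale).
#' @param tau2,sigma2 session and residual variance components.
#' @return Non-negative effect size d (the sign lives in the contrast).
#' @export
cohens_d_mixed <- function(estimate, tau2, sigma2) {
  total <- tau2 + sigma2
  if (total <= 0) stop("zero total variance; d undefined")
  abs(estimate) / sqrt(total)
}

#' Label an effect size
#'
#' Thresholds with closed lower bounds: small >= 0.20, medium >= 0.50,
#' large >= 0.80; below 0.20 is trivial.
#'
#' @param d non-negative effect size(s).
#' @return Character vector in `{trivial, small, medium, large}`.
#' @export
classify_effect <- function(d) {
  stopifnot(all(d >= 0))
  cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("trivial", "small", "medium", "large")) |> as.character()
}

#' Serialize a fitted model to JSON
#'
#' @param object a `ski_mixed`.
#' @param path output JSON path.
#' @param contrasts optional contrast table (from [tukey_contrasts()]).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(object, path, contrasts = NULL) {
  payload <- list(response = object$response, transform = object$transform,
                  fixed = deparse(object$fixed),
                  beta = as.list(object$beta), tau2 = object$tau2,
                  sigma2 = object$sigma2, anova = object$anova,
                  emmeans = estimated_marginal_means(object),
                  contrasts = contrasts, messages = object$messages)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
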