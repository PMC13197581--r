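#' Pearson correlation between two site-table columns
#'
#' Complete-case Pearson correlation with the usual two-tailed t-test on
#' n - 2 degrees of freedom.
#'
#' @param data a data frame.
#' @param x,y column names (unquoted or strings).
#' @return a one-row tibble: `r`, `statistic`, `df`, `p_value`, `n`.
#' @examples
#' pearson_cor(port_phillip_sites(), seed_density, spathe_density)
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in a variable.", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = length(xv))
}

#' Beta regression with a logit link
#'
#' Maximum-likelihood fit of a beta law for a response in (0, 1) — here
#' genotypic richness R — with mean mu = plogis(X beta) and a constant
#' precision phi: y ~ Beta(mu * phi, (1 - mu) * phi).  Standard errors come
#' from the observed information (numerical Hessian of the log-likelihood,
#' computed on an internally standardized design for conditioning and
#' mapped back).  Responses on the boundary are squeezed inward with
#' y' = (y (n - 1) + 0.5) / n before fitting.
#'
#' @param data a data frame (e.g. a site table).
#' @param formula model formula, e.g. `r ~ log(seed_density) + log(inflow)`.
#'   Rows with missing values in any model variable are dropped listwise.
#' @param link only `"logit"` is implemented.
#' @return an object of class `beta_reg` with methods `print()`, `coef()`,
#'   `logLik()`, `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' fit <- beta_regression(port_phillip_sites(), r ~ seed_density + inflow)
#' glance(fit)
#' @export
beta_regression <- function(data, formula, link = "logit") {
  if (link != "logit") stop("only the logit link is implemented.", call. = FALSE)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient.", call. = FALSE)
  if (n <= p + 1) stop("too few observations for ", p + 1, " parameters.",
                       call. = FALSE)
  squeezed <- FALSE
  if (any(y <= 0 | y >= 1)) {
    if (any(y < 0 | y > 1)) stop("response must lie in [0, 1].", call. = FALSE)
    y <- (y * (n - 1) + 0.5) / n
    squeezed <- TRUE
  }
  # standardize non-intercept columns for optimizer conditioning
  has_int <- "(Intercept)" %in% colnames(X)
  ctr <- rep(0, p); scl <- rep(1, p)
  vary <- apply(X, 2, stats::sd) > 0
  std_cols <- which(vary & colnames(X) != "(Intercept)")
  ctr[std_cols] <- colMeans(X[, std_cols, drop = FALSE])
  scl[std_cols] <- apply(X[, std_cols, drop = FALSE], 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  nll <- function(par) {
    mu <- stats::plogis(drop(Xs %*% par[1:p]))
    phi <- exp(par[p + 1])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  beta0 <- stats::coef(stats::lm.fit(Xs, stats::qlogis(y)))
  mu0 <- stats::plogis(drop(Xs %*% beta0))
  v0 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v0, 1e-8) - 1, 2)
  opt <- stats::nlminb(c(beta0, log(phi0)), nll,
                       control = list(iter.max = 1000, eval.max = 1000))
  if (opt$convergence != 0 && !grepl("converg", opt$message, ignore.case = TRUE)) {
    stop("beta regression did not converge: ", opt$message, call. = FALSE)
  }
  h <- stats::optimHess(opt$par, nll)
  vcov_s <- tryCatch(solve(h), error = function(e) matrix(NA, p + 1, p + 1))
  # map standardized-scale estimates back to the original design
  J <- diag(p + 1)
  for (j in std_cols) J[j, j] <- 1 / scl[j]
  if (has_int) {
    i0 <- which(colnames(X) == "(Intercept)")
    J[i0, std_cols] <- -ctr[std_cols] / scl[std_cols]
  }
  par_orig <- drop(J %*% opt$par)
  vcov_o <- J %*% vcov_s %*% t(J)
  beta <- par_orig[1:p]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(vcov_o)[1:p], 0))
  phi <- exp(opt$par[p + 1])
  eta <- drop(X %*% beta)
  fit <- structure(list(
    coefficients = beta, std_error = se, z_value = beta / se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    phi = phi, phi_se = phi * sqrt(max(diag(vcov_s)[p + 1], 0, na.rm = TRUE)),
    log_lik = -opt$objective, nobs = n, k = p + 1,
    linear_predictor = eta, fitted = stats::plogis(eta),
    y = y, squeezed = squeezed,
    formula = formula, terms = attr(mf, "terms"),
    vcov = vcov_o[1:p, 1:p, drop = FALSE],
    call = match.call()
  ), class = "beta_reg")
  fit$aicc <- aicc(fit)
  fit$pseudo_r2 <- pseudo_r2(fit)
  fit
}

#' Pseudo R-squared of a beta regression
#'
#' Squared Pearson correlation between the linear predictor and the
#' link-transformed response; 0 for an intercept-only fit.
#'
#' @param fit a `beta_reg` object.
#' @return a number in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "beta_reg"))
  if (stats::sd(fit$linear_predictor) == 0) return(0)
  stats::cor(fit$linear_predictor, stats::qlogis(fit$y))^2
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k + 1)/(n - k - 1), with k counting all estimated
#' parameters (regression coefficients plus the precision phi).
#'
#' @param fit a `beta_reg` object.
#' @return the AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "beta_reg"))
  k <- fit$k; n <- fit$nobs
  -2 * fit$log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit link),", x$nobs, "observations\n")
  print(tidy.beta_reg(x), n = Inf)
  cat(sprintf("phi = %.2f, logLik = %.3f, AICc = %.2f, pseudo-R2 = %.3f\n",
              x$phi, x$log_lik, x$aicc, x$pseudo_r2))
  invisible(x)
}

#' @export
coef.beta_reg <- function(object, ...) object$coefficients

#' @export
logLik.beta_reg <- function(object, ...) {
  structure(object$log_lik, df = object$k, nobs = object$nobs,
            class = "logLik")
}

#' @export
vcov.beta_reg <- function(object, ...) object$vcov

#' Tidy a beta-regression fit
#'
#' @param x a `beta_reg` object.
#' @param ... unused.
#' @return a tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`.
#' @export
tidy.beta_reg <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = x$std_error,
                 statistic = unname(x$z_value),
                 p.value = unname(x$p_value))
}

#' Glance at a beta-regression fit
#'
#' @param x a `beta_reg` object.
#' @param ... unused.
#' @return a one-row tibble: `pseudo.r.squared`, `phi`, `logLik`, `AICc`,
#'   `df`, `nobs`.
#' @export
glance.beta_reg <- function(x, ...) {
  tibble::tibble(pseudo.r.squared = x$pseudo_r2, phi = x$phi,
                 logLik = x$log_lik, AICc = x$aicc, df = x$k,
                 nobs = x$nobs)
}

#' All-subsets model selection by AICc
#'
#' Fits a beta regression for every subset of the candidate predictors
#' (including the intercept-only null) and ranks models by AICc, with
#' AICc differences and Akaike weights.
#'
#' @param data a data frame.
#' @param formula full model formula; its right-hand-side terms are the
#'   candidate set (at most 10).
#' @return a tibble ranked by AICc: `model`, `k`, `logLik`, `AICc`,
#'   `delta`, `weight`, `pseudo_r2`.
#' @export
select_models <- function(data, formula) {
  tt <- stats::terms(formula, data = data)
  cand <- attr(tt, "term.labels")
  if (length(cand) > 10) stop("at most 10 candidate predictors.", call. = FALSE)
  response <- deparse(formula[[2]])
  subsets <- unlist(lapply(0:length(cand), function(k)
    utils::combn(cand, k, simplify = FALSE)), recursive = FALSE)
  rows <- purrr::map(subsets, function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- tryCatch(beta_regression(data, f), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("skipping model ", rhs, ": ", conditionMessage(fit),
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(model = paste(response, "~", rhs), k = fit$k,
                   logLik = fit$log_lik, AICc = fit$aicc,
                   pseudo_r2 = fit$pseudo_r2)
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$AICc)
  out |>
    dplyr::mutate(delta = .data$AICc - min(.data$AICc),
                  weight = exp(-.data$delta / 2) /
                    sum(exp(-.data$delta / 2))) |>
    dplyr::select("model", "k", "logLik", "AICc", "delta", "weight",
                  "pseudo_r2")
}

#' Greedy collinearity screen
#'
#' While any pair of predictors has |Pearson r| at or above the
#' threshold, drops the member of the most correlated pair whose mean
#' absolute correlation with the remaining predictors is larger, and logs
#' the exclusion.  Used to thin a covariate set (e.g. spathe density,
#' node degree and expected heterozygosity shadowing other predictors)
#' before model selection.
#'
#' @param data a data frame.
#' @param vars character vector of predictor columns (default: all
#'   numeric columns).
#' @param r_threshold absolute-correlation cutoff (default 0.7).
#' @return a list with `retained` (character) and `dropped` (tibble
#'   `variable`, `partner`, `r`).
#' @export
collinearity_screen <- function(data, vars = NULL, r_threshold = 0.7) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(vars) < 2) stop("need at least 2 predictors.", call. = FALSE)
  dropped <- tibble::tibble(variable = character(), partner = character(),
                            r = double())
  keep <- vars
  repeat {
    cm <- stats::cor(data[keep], use = "pairwise.complete.obs")
    diag(cm) <- 0
    if (max(abs(cm)) < r_threshold) break
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(abs(cm[pair, , drop = FALSE]))
    drop_var <- pair[which.max(mean_abs)]
    partner <- setdiff(pair, drop_var)[1]
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = drop_var, partner = partner,
      r = cm[drop_var, partner]))
    keep <- setdiff(keep, drop_var)
    if (length(keep) < 2) break
  }
  list(retained = keep, dropped = dropped)
}
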