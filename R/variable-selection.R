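# AICc-guided selection of climatic variables via an L1-penalized
# occurrence-versus-background model (linear + quadratic features), iteratively
# removing correlated and low-contribution variables.

#' Fit a penalized occurrence-versus-background model
#'
#' A Maxent-style surrogate: logistic regression of occurrence sites against
#' background sites on linear and quadratic features of the variables
#' (standardized over the background), with an L1 penalty scaled by the
#' regularization multiplier `beta`. The reported log-likelihood is the
#' Maxent convention: the log probability of each occurrence's cell under the
#' exponential model normalized over the background.
#'
#' @param env_occ occurrence-site environment matrix (sites x variables).
#' @param env_bg background environment matrix (same columns).
#' @param variables variables to use (default: all shared columns).
#' @param beta regularization multiplier (> 0); larger shrinks harder.
#' @return an object of class `maxent_like_model` with elements
#'   `coefficients` (named, nonzero features only), `beta`, `loglik`, `k`
#'   (number of nonzero coefficients), `n` (occurrence count), `variables`.
#' @export
fit_occurrence_model <- function(env_occ, env_bg, variables = NULL, beta = 1) {
  stopifnot(beta > 0)
  if (is.null(variables)) variables <- colnames(env_occ)
  miss <- setdiff(variables, intersect(colnames(env_occ), colnames(env_bg)))
  if (length(miss))
    stop("variables absent from the matrices: ", paste(miss, collapse = ", "),
         call. = FALSE)
  occ <- as.matrix(env_occ[, variables, drop = FALSE])
  bg <- as.matrix(env_bg[, variables, drop = FALSE])
  if (nrow(occ) < 2) stop("need at least 2 occurrence sites", call. = FALSE)

  sds <- apply(bg, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("dropping constant variable(s) over the background: ",
            paste(variables[flat], collapse = ", "), call. = FALSE)
    variables <- variables[!flat]
    if (length(variables) == 0)
      stop("no non-constant variables left", call. = FALSE)
    occ <- occ[, variables, drop = FALSE]
    bg <- bg[, variables, drop = FALSE]
    sds <- sds[!flat]
  }
  ctr <- colMeans(bg)
  feat <- function(m) {
    s <- sweep(sweep(m, 2, ctr), 2, sds, "/")
    q <- s^2
    colnames(q) <- paste0(colnames(m), "^2")
    cbind(s, q)
  }
  x_occ <- feat(occ); x_bg <- feat(bg)
  n_occ <- nrow(x_occ); n_bg <- nrow(x_bg)
  x <- rbind(x_occ, x_bg)
  y <- c(rep(1, n_occ), rep(0, n_bg))
  w <- c(rep(1 / n_occ, n_occ), rep(1 / n_bg, n_bg))  # class-balanced

  # map the Maxent regularization multiplier to the glmnet penalty scale:
  # per-feature penalty ~ beta / sqrt(n_occ) for unit-variance features
  # (independent of the number of candidate features, as in Maxent)
  lambda <- beta / (4 * sqrt(n_occ))
  fit <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12)
  coefs <- as.numeric(fit$beta)
  names(coefs) <- rownames(fit$beta)
  nz <- coefs[coefs != 0]

  # Maxent-style loglik: occurrence probability normalized over background
  eta_occ <- as.numeric(x_occ %*% coefs)
  eta_bg <- as.numeric(x_bg %*% coefs)
  m <- max(eta_bg)
  log_norm <- m + log(sum(exp(eta_bg - m)))
  loglik <- sum(eta_occ - log_norm)

  structure(
    list(coefficients = nz, all_coefficients = coefs, beta = beta,
         loglik = loglik, k = length(nz), n = n_occ,
         variables = variables, center = ctr, scale = sds),
    class = "maxent_like_model")
}

#' @export
print.maxent_like_model <- function(x, ...) {
  cat("<maxent_like_model> beta=", x$beta, ", k=", x$k, " nonzero features, ",
      "n=", x$n, " occurrences, loglik=", signif(x$loglik, 6), "\n", sep = "")
  invisible(x)
}

#' Per-variable contribution of a fitted model
#'
#' Share of the summed absolute coefficient mass (features are unit-variance
#' over the background, so |coefficient| is comparable across features);
#' linear and quadratic features of one variable are pooled.
#'
#' @param model a `maxent_like_model`.
#' @return named numeric vector summing to 1 (all zero if the model is empty).
#' @export
variable_contribution <- function(model) {
  contrib <- vapply(model$variables, function(v) {
    idx <- names(model$all_coefficients) %in% c(v, paste0(v, "^2"))
    sum(abs(model$all_coefficients[idx]))
  }, numeric(1))
  tot <- sum(contrib)
  if (tot > 0) contrib / tot else contrib
}

#' Small-sample-corrected Akaike Information Criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`; defined only when
#' `n - k - 1 > 0`.
#'
#' @param loglik model log-likelihood.
#' @param k number of (nonzero) parameters.
#' @param n sample size (occurrence count).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 = ", n - k - 1, " (need > 0)",
         call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select climatic variables by AICc over penalized models
#'
#' Iteratively: (1) fit the occurrence-versus-background model on the current
#' variable set for each regularization multiplier and score it by AICc;
#' (2) from the best model of the iteration take per-variable contributions;
#' (3) among background-correlated pairs (|Pearson r| > `corr_threshold`)
#' remove the lower-contribution member, and remove variables contributing
#' less than `contrib_threshold`; repeat until no variable is removed or the
#' iteration's best AICc stops improving. The returned set/beta is the
#' minimum-AICc entry of the whole trace.
#'
#' @param env_occ,env_bg occurrence and background environment matrices.
#' @param betas regularization multipliers to scan.
#' @param corr_threshold absolute Pearson correlation above which a pair is
#'   considered redundant.
#' @param contrib_threshold minimum contribution share to keep a variable.
#' @param max_background background cells are capped at this size by a seeded
#'   subsample for tractability.
#' @param seed integer seed (background subsample).
#' @return an object of class `selection_result`: `selected_variables`,
#'   `winning_beta`, `aicc_trace` (data.frame), `corr_threshold`,
#'   `contrib_threshold`.
#' @export
select_variables <- function(env_occ, env_bg, betas = 1:6,
                             corr_threshold = 0.7, contrib_threshold = 0.05,
                             max_background = 10000, seed = 1L) {
  vars <- intersect(colnames(env_occ), colnames(env_bg))
  if (length(vars) < 1) stop("no shared candidate variables", call. = FALSE)
  if (nrow(env_bg) > max_background) {
    keep <- with_seed(child_seed(seed, "bgsub"),
                      sample.int(nrow(env_bg), max_background))
    env_bg <- env_bg[keep, , drop = FALSE]
  }

  # variables violating the redundancy rule within a set (|r| > threshold
  # pairs over the background)
  correlated_pairs <- function(set) {
    if (length(set) < 2) return(NULL)
    r <- stats::cor(env_bg[, set, drop = FALSE])
    which(abs(r) > corr_threshold & upper.tri(r), arr.ind = TRUE)
  }

  trace <- list()
  iter <- 0L
  current <- vars
  repeat {
    iter <- iter + 1L
    fits <- lapply(betas, function(b)
      fit_occurrence_model(env_occ, env_bg, current, beta = b))
    scores <- vapply(fits, function(f) {
      if (f$n - f$k - 1 <= 0) return(NA_real_)
      aicc(f$loglik, f$k, f$n)
    }, numeric(1))
    pairs <- correlated_pairs(current)
    contribs <- lapply(fits, variable_contribution)
    for (i in seq_along(betas)) {
      # a model may win only if it violates neither selection rule
      eligible <- is.null(pairs) || nrow(pairs) == 0
      eligible <- eligible && all(contribs[[i]] >= contrib_threshold)
      trace[[length(trace) + 1]] <- data.frame(
        iteration = iter, beta = betas[i], n_vars = length(current),
        k = fits[[i]]$k, aicc = scores[i], eligible = eligible,
        variables = paste(current, collapse = ";"))
    }
    if (all(is.na(scores)))
      stop("AICc undefined for every beta (too few occurrences for the ",
           "retained features)", call. = FALSE)
    contrib <- contribs[[which.min(scores)]]

    drop <- names(contrib)[contrib < contrib_threshold]
    if (!is.null(pairs) && nrow(pairs)) {
      ord <- order(vapply(seq_len(nrow(pairs)), function(p)
        max(contrib[current[pairs[p, ]]]), numeric(1)), decreasing = TRUE)
      marked <- character(0)
      for (p in ord) {
        a <- current[pairs[p, 1]]; b <- current[pairs[p, 2]]
        if (a %in% marked || b %in% marked) next
        marked <- c(marked, if (contrib[a] <= contrib[b]) a else b)
      }
      drop <- union(drop, marked)
    }
    remaining <- setdiff(current, intersect(drop, current))
    if (length(remaining) == length(current)) break
    if (length(remaining) == 0)
      stop("all variables removed; loosen corr_threshold or ",
           "contrib_threshold", call. = FALSE)
    current <- remaining
  }

  trace_df <- do.call(rbind, trace)
  ok <- which(!is.na(trace_df$aicc) & trace_df$eligible)
  if (length(ok) == 0) ok <- which(!is.na(trace_df$aicc))
  # minimal AICc among rule-satisfying models; exact ties broken toward
  # parsimony, then the later (more reduced) iteration
  win <- ok[order(trace_df$aicc[ok], trace_df$n_vars[ok],
                  -trace_df$iteration[ok])[1]]
  structure(
    list(selected_variables = strsplit(trace_df$variables[win], ";")[[1]],
         winning_beta = trace_df$beta[win],
         aicc_trace = trace_df,
         corr_threshold = corr_threshold,
         contrib_threshold = contrib_threshold),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected_variables), " variables @ beta=",
      x$winning_beta, " (AICc ", signif(min(x$aicc_trace$aicc, na.rm = TRUE), 6),
      ")\n  ", paste(x$selected_variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `selection_result`.
#' @param path output file.
#' @export
write_selection_json <- function(result, path) {
  jsonlite::write_json(
    list(selected_variables = result$selected_variables,
         winning_beta = result$winning_beta,
         corr_threshold = result$corr_threshold,
         contrib_threshold = result$contrib_threshold,
         aicc_trace = result$aicc_trace),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
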