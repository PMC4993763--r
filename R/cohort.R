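#' Mann-Whitney U test with rank-biserial effect size
#'
#' U counts the pairs (a, b) with `b > a` plus half of the ties, where `a`
#' ranges over `group_a` and `b` over `group_b`; the rank-biserial
#' correlation is `r = 2U / (n_a * n_b) - 1`, so r = +1 means every value
#' in `group_b` exceeds every value in `group_a`. For small problems
#' (`n_a * n_b <= 64`) the p-value is exact, from full enumeration of the
#' permutation distribution of U under the null (midranks handle ties);
#' larger problems use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param group_a,group_b numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (group_b tends
#'   larger) or `"less"`.
#' @return A one-row tibble with columns `U`, `p`, `r`, `n_a`, `n_b`,
#'   `method`.
#' @export
mann_whitney <- function(group_a, group_b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(group_a[!is.na(group_a)])
  b <- as.numeric(group_b[!is.na(group_b)])
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop_domain("both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[(na + 1L):(na + nb)]) - nb * (nb + 1) / 2
  r <- 2 * U / (na * nb) - 1
  mu <- na * nb / 2
  if (na * nb <= 64) {
    method <- "exact enumeration"
    combs <- utils::combn(na + nb, nb)
    wsums <- colSums(matrix(rk[combs], nrow = nb))
    Us <- wsums - nb * (nb + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      greater = mean(Us >= U - eps),
      less = mean(Us <= U + eps)
    )
  } else {
    method <- "normal approximation"
    n <- na + nb
    ties <- table(pooled)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tiecor))
    z <- U - mu
    cc <- 0.5 * sign(z)
    z <- (z - cc) / sigma
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(1, p)
  }
  tibble(U = U, p = p, r = r, n_a = na, n_b = nb, method = method)
}

# stable P(B) = 1 / (1 + a * exp(b*x + c*y))
scenario_probability <- function(a, b, c, x, y) {
  plogis(-(log(a) + b * x + c * y))
}

new_dyad_classifier <- function(a, b, c, beta, separation, data, positive,
                                boot = NULL, n_boot = 0L, seed = NULL, oob = NA) {
  structure(
    list(a = a, b = b, c = c, beta = beta, separation = separation,
         data = data, positive = positive, boot = boot, n_boot = n_boot,
         seed = seed, oob = oob),
    class = "dyad_classifier"
  )
}

fit_glm_abc <- function(df, positive) {
  z <- as.integer(df$label == positive)
  fit <- suppressWarnings(glm(z ~ x + y, data = df, family = binomial()))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0          # dropped (constant/collinear) feature
  sep <- !fit$converged || any(abs(beta[-1]) > 25) ||
    fit$boundary
  list(beta = beta, a = exp(-beta[[1]]), b = -beta[[2]], c = -beta[[3]],
       separation = sep)
}

# P(B) on the logit scale, robust to huge separated coefficients
prob_from_beta <- function(beta, x, y) {
  plogis(beta[[1]] + beta[[2]] * x + beta[[3]] * y)
}

#' Fit the two-feature logistic interaction-style classifier
#'
#' Fits a maximum-likelihood logistic regression of the scenario label on
#' the synchrony feature x (= c(0)) and the entrainment feature y (= the
#' cross-correlation centre of mass, seconds), and reparameterizes the
#' coefficients as the probability function `P(B) = 1 / (1 + a *
#' exp(b*x + c*y))` via `a = exp(-beta0)`, `b = -beta1`, `c = -beta2`. The
#' decision boundary is the line `b*x + c*y = -log(a)`.
#'
#' @param data data frame with columns `x`, `y` and `label`.
#' @param positive the label treated as the positive class B.
#' @return An object of class `dyad_classifier`; its `separation` flag is
#'   set when the classes are perfectly separable (coefficients unbounded).
#' @export
fit_classifier <- function(data, positive = "B") {
  df <- as.data.frame(data)
  if (!all(c("x", "y", "label") %in% names(df))) {
    stop_format("`data` needs columns x, y, label")
  }
  df <- df[stats::complete.cases(df[c("x", "y", "label")]), ]
  if (nrow(df) < 4L) stop_domain("need at least 4 labelled dyads")
  if (length(unique(df$label)) < 2L) stop_domain("both class labels must be present")
  f <- fit_glm_abc(df, positive)
  if (f$separation) {
    warning("classes are perfectly separated; (a, b, c) are unbounded", call. = FALSE)
  }
  new_dyad_classifier(f$a, f$b, f$c, f$beta, f$separation, df, positive)
}

#' Predict the probability of scenario B
#'
#' @param object a `dyad_classifier`.
#' @param newdata data frame with columns `x` and `y` (defaults to the
#'   training data).
#' @param ... unused.
#' @return A numeric vector of probabilities in (0, 1).
#' @export
predict.dyad_classifier <- function(object, newdata = NULL, ...) {
  nd <- newdata %||% object$data
  if (!is.null(object$beta)) return(prob_from_beta(object$beta, nd$x, nd$y))
  scenario_probability(object$a, object$b, object$c, nd$x, nd$y)
}

#' Bootstrap the classifier parameters and accuracy
#'
#' Resamples dyads with replacement `n_boot` times, refits the classifier
#' on each replicate and records (a, b, c) together with the
#' classification accuracy at threshold P = 0.5. Accuracy is evaluated
#' out-of-bag by default (on the dyads not drawn into the replicate);
#' `oob = FALSE` scores the replicate in-sample. Replicates that draw a
#' single class are redrawn (and counted), keeping `n_boot` fixed. The
#' whole procedure is deterministic given `seed`.
#'
#' @inheritParams fit_classifier
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param oob evaluate accuracy out-of-bag.
#' @return A `dyad_classifier` whose `boot` field is a tibble with one row
#'   per replicate (`a`, `b`, `c`, `accuracy`).
#' @export
bootstrap_classifier <- function(data, positive = "B", n_boot = 1000L,
                                 seed = 1L, oob = TRUE) {
  model <- fit_classifier(data, positive)
  df <- model$data
  n <- nrow(df)
  redrawn <- 0L
  boot <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(df$label[idx])) > 1L) break
        redrawn <<- redrawn + 1L
      }
      f <- fit_glm_abc(df[idx, ], positive)
      eval_idx <- if (oob) setdiff(seq_len(n), idx) else idx
      if (!length(eval_idx)) eval_idx <- seq_len(n)
      p <- prob_from_beta(f$beta, df$x[eval_idx], df$y[eval_idx])
      truth <- df$label[eval_idx] == positive
      tibble(a = f$a, b = f$b, c = f$c,
             accuracy = mean((p >= 0.5) == truth),
             separation = f$separation)
    })
  })
  if (redrawn > 0L) {
    message(sprintf("redrew %d degenerate single-label bootstrap replicate(s)", redrawn))
  }
  model$boot <- boot
  model$n_boot <- as.integer(n_boot)
  model$seed <- seed
  model$oob <- oob
  model
}

#' @export
print.dyad_classifier <- function(x, ...) {
  cat(sprintf(
    "<dyad_classifier> P(%s) = 1 / (1 + a exp(b x + c y)); a = %.3g, b = %.3g, c = %.3g%s\n",
    x$positive, x$a, x$b, x$c,
    if (x$separation) " [perfect separation]" else ""
  ))
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap (n = %d, %s): accuracy %.1f%% +/- %.1f%%\n",
                x$n_boot, if (isTRUE(x$oob)) "out-of-bag" else "in-sample",
                100 * mean(x$boot$accuracy), 100 * sd(x$boot$accuracy)))
  }
  invisible(x)
}

#' @export
tidy.dyad_classifier <- function(x, ...) {
  est <- c(a = x$a, b = x$b, c = x$c)
  out <- tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$boot)) {
    out$std.error <- c(sd(x$boot$a), sd(x$boot$b), sd(x$boot$c))
    out$boot.mean <- c(mean(x$boot$a), mean(x$boot$b), mean(x$boot$c))
  }
  out
}

#' @export
glance.dyad_classifier <- function(x, ...) {
  tibble(
    n = nrow(x$data),
    n_boot = x$n_boot,
    oob = x$oob,
    separation = x$separation,
    accuracy_mean = if (!is.null(x$boot)) mean(x$boot$accuracy) else NA_real_,
    accuracy_sd = if (!is.null(x$boot)) sd(x$boot$accuracy) else NA_real_
  )
}
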