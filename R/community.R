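#' Euclidean distance matrix for station-level responses
#'
#' @param x Numeric vector (univariate response) or matrix/data frame with
#'   one row per sample; all values must be finite.
#' @return A `dist` object with attribute `metric = "euclidean"`.
#' @export
euclidean_distance_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("response must be numeric")
  if (nrow(m) < 2L) stop("need at least two samples")
  if (any(!is.finite(m))) stop("response contains non-finite values")
  d <- stats::dist(m, method = "euclidean")
  attr(d, "metric") <- "euclidean"
  d
}

# tr(H G) for symmetric H, G
tr_prod <- function(H, G) sum(H * G)

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Two-factor crossed PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a crossed two-factor
#' design, on the Gower-centered inner-product matrix of the supplied
#' distances. Sums of squares are partitioned sequentially (main effect A,
#' then B, then the A:B interaction); each term's pseudo-F is its mean
#' square over the residual mean square, and significance is assessed by
#' unrestricted permutation of the observations. With Euclidean distances
#' on a univariate response and a balanced design the pseudo-F statistics
#' coincide with the classical two-way ANOVA F.
#'
#' Permutation p-values follow the add-one convention,
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (B + 1)}, and therefore lie in
#' `[1/(B+1), 1]`. The number of distinct permutations actually sampled is
#' reported per the output's `Perm` column.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param factor_a,factor_b Factors (or coercible) aligned with the rows of
#'   `d`, each with >= 2 levels; every cell of the crossed design must be
#'   non-empty.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @param term_names Length-2 labels for the two factors in the output.
#' @return An object of class `permanova_table`: a data frame with rows for
#'   each term and the residual, and columns `df`, `SS`, `MS`, `pseudo_F`,
#'   `p_perm`, `n_unique_perm`.
#' @examples
#' set.seed(1)
#' y <- rnorm(24)
#' a <- gl(3, 8); b <- gl(2, 4, 24)
#' permanova_two_way(euclidean_distance_matrix(y), a, b, n_perm = 199, seed = 1)
#' @export
permanova_two_way <- function(d, factor_a, factor_b, n_perm = 9999,
                              seed = NULL, term_names = c("A", "B")) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("d must be a symmetric distance matrix or dist object")
  n <- nrow(D)
  a <- as.factor(factor_a)
  b <- as.factor(factor_b)
  if (length(a) != n || length(b) != n)
    stop("factor labels must align with the distance matrix")
  if (nlevels(droplevels(a)) < 2L || nlevels(droplevels(b)) < 2L)
    stop("each factor needs at least two observed levels")
  tab <- table(a, b)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("confounded design: empty cell %s x %s",
                 rownames(tab)[empty[1L]], colnames(tab)[empty[2L]]))
  }

  # Gower-centered inner-product matrix
  A2 <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A2 %*% C

  H_a    <- hat_matrix(stats::model.matrix(~a))
  H_ab   <- hat_matrix(stats::model.matrix(~a + b))
  H_full <- hat_matrix(stats::model.matrix(~a * b))
  I_n <- diag(n)

  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_int <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  if (df_res < 1L) stop("no residual degrees of freedom")

  ss_terms <- function(G) {
    c(tr_prod(H_a, G),
      tr_prod(H_ab - H_a, G),
      tr_prod(H_full - H_ab, G),
      tr_prod(I_n - H_full, G))
  }
  ss <- ss_terms(G)
  df <- c(df_a, df_b, df_int, df_res)
  ms <- ss / df
  F_obs <- ms[1:3] / ms[4L]

  if (!is.null(seed)) set.seed(seed)
  exceed <- c(0L, 0L, 0L)
  perm_keys <- character(n_perm)
  for (r in seq_len(n_perm)) {
    p <- sample.int(n)
    perm_keys[r] <- paste(p, collapse = ",")
    Gp <- G[p, p]
    ssp <- ss_terms(Gp)
    Fp <- (ssp[1:3] / df[1:3]) / (ssp[4L] / df[4L])
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  p_perm <- (1 + exceed) / (n_perm + 1)
  n_unique <- length(unique(perm_keys))

  out <- data.frame(
    term = c(term_names[1L], term_names[2L],
             paste(term_names, collapse = " x "), "Residual"),
    df = df, SS = ss, MS = ms,
    pseudo_F = c(F_obs, NA_real_),
    p_perm = c(p_perm, NA_real_),
    n_unique_perm = c(rep(n_unique, 3L), NA_integer_),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova_table", "data.frame")
  attr(out, "n_perm") <- n_perm
  attr(out, "SS_total") <- tr_prod(I_n, G)
  out
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("Two-factor PERMANOVA (sequential SS, unrestricted permutation)\n")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}

#' BIOENV best-subset selection of environmental correlates
#'
#' Finds the subset of (z-scored) environmental variables whose Euclidean
#' inter-sample distance pattern best rank-correlates (Spearman's rho) with
#' the response distance pattern, by exhaustive search over all non-empty
#' subsets. Variables named in `exclude` are removed before the search
#' (e.g. a prey density already deterministically encoded in an encounter
#' rate); constant variables are dropped with a warning.
#'
#' @param env Data frame of per-sample environmental variables (numeric).
#' @param d_response A `dist` object or distance matrix for the response.
#' @param exclude Character vector of variable names to exclude.
#' @param max_subset_size Optional cap on subset size searched.
#' @param n_perm If > 0, a permutation p-value for the best rho is computed
#'   by shuffling sample identities of the response distances and redoing
#'   the full search (accounts for selection bias).
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `bioenv_result`: a list with `best_vars`,
#'   `rho`, `p_perm` (NA if `n_perm = 0`), and `trace`, a data frame of all
#'   subsets searched ranked by rho.
#' @export
bioenv_best <- function(env, d_response, exclude = character(),
                        max_subset_size = NULL, n_perm = 0, seed = NULL) {
  env <- as.data.frame(env)
  if (!all(vapply(env, is.numeric, logical(1L))))
    stop("all environmental variables must be numeric")
  if (any(!is.finite(as.matrix(env)))) stop("environmental variables must be finite")
  unknown <- setdiff(exclude, names(env))
  if (length(unknown))
    warning("excluded variables not present: ", paste(unknown, collapse = ", "))
  env <- env[, setdiff(names(env), exclude), drop = FALSE]
  constant <- vapply(env, function(v) stats::sd(v) == 0, logical(1L))
  if (any(constant)) {
    warning("dropping constant variable(s): ",
            paste(names(env)[constant], collapse = ", "))
    env <- env[, !constant, drop = FALSE]
  }
  if (ncol(env) < 1L) stop("no environmental variables left to search")
  Dresp <- as.matrix(d_response)
  if (nrow(Dresp) != nrow(env))
    stop("response distances do not align with the environmental table")
  resp_vec <- Dresp[lower.tri(Dresp)]
  Z <- scale(as.matrix(env))

  vars <- colnames(Z)
  k_max <- if (is.null(max_subset_size)) length(vars)
           else min(max_subset_size, length(vars))
  subsets <- list()
  for (k in seq_len(k_max))
    subsets <- c(subsets, utils::combn(vars, k, simplify = FALSE))

  rho_for <- function(rv) {
    vapply(subsets, function(s) {
      dv <- stats::dist(Z[, s, drop = FALSE])
      stats::cor(as.vector(dv), rv, method = "spearman")
    }, numeric(1L))
  }
  rhos <- rho_for(resp_vec)
  best <- which.max(rhos)

  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(Dresp)
    best_obs <- rhos[best]
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      p <- sample.int(n)
      rvp <- Dresp[p, p][lower.tri(Dresp)]
      exceed <- exceed + (max(rho_for(rvp)) >= best_obs - 1e-12)
    }
    p_perm <- (1 + exceed) / (n_perm + 1)
  }

  trace <- data.frame(
    subset = vapply(subsets, paste, character(1L), collapse = "+"),
    size = lengths(subsets),
    rho = rhos, stringsAsFactors = FALSE)
  trace <- trace[order(-trace$rho), ]
  rownames(trace) <- NULL
  structure(list(best_vars = subsets[[best]], rho = rhos[best],
                 p_perm = p_perm, trace = trace),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat("BIOENV best subset:", paste(x$best_vars, collapse = " + "),
      sprintf("(rho = %.3f", x$rho))
  if (!is.na(x$p_perm)) cat(sprintf(", p(perm) = %.4f", x$p_perm))
  cat(")\n")
  invisible(x)
}

#' Predator-prey size regression
#'
#' Ordinary least squares of prey length on predator length with a
#' two-sided t-test on the slope, the standard check for a size-structured
#' trophic relationship.
#'
#' @param pred_lengths Predator total lengths, mm.
#' @param prey_lengths Prey total lengths, mm, same length.
#' @return A list with `slope`, `intercept`, `t_value`, `p_value`, `n`, and
#'   the underlying `lm` fit.
#' @export
size_regression <- function(pred_lengths, prey_lengths) {
  stopifnot(is.numeric(pred_lengths), is.numeric(prey_lengths),
            length(pred_lengths) == length(prey_lengths))
  if (length(pred_lengths) < 3L) stop("need at least three predator-prey pairs")
  if (any(!is.finite(pred_lengths)) || any(!is.finite(prey_lengths)))
    stop("lengths must be finite")
  if (stats::sd(pred_lengths) == 0)
    stop("predator lengths have zero variance; slope is not estimable")
  fit <- stats::lm(prey_lengths ~ pred_lengths)
  sm <- summary(fit)$coefficients
  list(slope = sm["pred_lengths", "Estimate"],
       intercept = sm["(Intercept)", "Estimate"],
       t_value = sm["pred_lengths", "t value"],
       p_value = sm["pred_lengths", "Pr(>|t|)"],
       n = length(pred_lengths), fit = fit)
}
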