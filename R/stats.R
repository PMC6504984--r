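#' Dunn-Sidak family-wise correction
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons.
#'
#' @param p raw p-values.
#' @param m family size (default: `length(p)`).
#' @return adjusted p-values, clipped to \[0, 1\].
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

# Sidak-adjusted pairwise paired comparisons between columns of Y
pairwise_paired <- function(Y, labels = colnames(Y), conf_level = 0.95) {
  k <- ncol(Y)
  n <- nrow(Y)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  alpha_adj <- 1 - (1 - (1 - conf_level))^(1 / m) # per-test level
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- Y[, i1] - Y[, i2]
    se <- sd(d) / sqrt(n)
    tstat <- if (se > 0) mean(d) / se else ifelse(mean(d) == 0, 0, Inf)
    p <- 2 * pt(-abs(tstat), n - 1)
    tcrit <- qt(1 - alpha_adj / 2, n - 1)
    data.frame(pair = paste(labels[i1], labels[i2], sep = "-"),
               mean_difference = mean(d), std_error = se,
               t = tstat, p_uncorrected = p,
               p_sidak = sidak_adjust(p, m),
               ci_low = mean(d) - tcrit * se,
               ci_high = mean(d) + tcrit * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way decomposition: total sum of squares split
#' into condition, subject and residual parts;
#' `F = MS_condition / MS_residual` on `(k - 1), (k - 1)(n - 1)`
#' degrees of freedom. Includes Greenhouse-Geisser epsilon and the
#' corrected p-value, plus Sidak-adjusted pairwise paired comparisons
#' with confidence intervals.
#'
#' @param Y numeric `n_subjects x k_conditions` matrix (each row one
#'   subject measured under every condition).
#' @return list with `anova` (one-row data.frame: `effect`, `F`,
#'   `df_num`, `df_den`, `gg_epsilon`, `p_uncorrected`, `p_gg`, SS
#'   components) and `pairwise`.
#' @export
rm_anova_oneway <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L || n < 2L)
    mf_stop("mf_design_error", "need >= 2 conditions and >= 2 subjects")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("c", seq_len(k))
  grand <- mean(Y)
  ss_total <- sum((Y - grand)^2)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_res <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- f_ratio(ss_cond, df1, ss_res, df2, 1e-12 * (ss_total + 1))
  eps <- gg_epsilon(Y)
  res <- data.frame(
    effect = "condition", F = Fv, df_num = df1, df_den = df2,
    gg_epsilon = eps,
    p_uncorrected = pf_upper(Fv, df1, df2),
    p_gg = pf_upper(Fv, eps * df1, eps * df2),
    ss_condition = ss_cond, ss_subject = ss_subj, ss_residual = ss_res,
    ss_total = ss_total, stringsAsFactors = FALSE)
  list(anova = res, pairwise = pairwise_paired(Y))
}

pf_upper <- function(f, df1, df2) {
  if (!is.finite(f)) return(0)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

# F statistic with the degenerate limits pinned down: a null effect is
# F = 0 even when the error SS is also 0 (constant or exactly additive
# data); eps absorbs accumulated floating-point residue
f_ratio <- function(ss_eff, df1, ss_err, df2, eps = 0) {
  if (ss_eff <= eps) return(0)
  if (ss_err <= eps) return(Inf)
  (ss_eff / df1) / (ss_err / df2)
}

# Greenhouse-Geisser epsilon from the covariance of contrast-transformed
# responses: eps = tr(S)^2 / (q * tr(S^2)), S = C cov(Y) C', C orthonormal
gg_epsilon <- function(Y, C = NULL) {
  k <- ncol(Y)
  if (is.null(C)) C <- orth_contrasts(k)
  gg_epsilon_cov(stats::cov(Y), C)
}

# epsilon from an explicit covariance matrix (exactly 1 under compound
# symmetry / sphericity)
gg_epsilon_cov <- function(Sigma, C) {
  S <- C %*% Sigma %*% t(C)
  q <- nrow(C)
  tr <- sum(diag(S))
  denom <- q * sum(S * S)
  if (denom <= 0) return(1)
  max(1 / q, min(1, tr^2 / denom))
}

# orthonormal contrast matrix, (k-1) x k (Helmert, normalized)
orth_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  t(H) / sqrt(colSums(H^2))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject two-factor design. Each effect (two main
#' effects and the interaction) is tested against its own
#' effect-by-subject error term; the Greenhouse-Geisser epsilon is
#' estimated from the covariance of the effect's contrast-transformed
#' responses and applied to both degrees of freedom.
#'
#' @param Y 3-D array `n_subjects x a x b` (factor A, e.g. modality,
#'   by factor B, e.g. threshold), complete and balanced.
#' @param names_a,names_b optional level labels.
#' @return data.frame with one row per effect (`A`, `B`, `A:B`):
#'   `F`, `df_num`, `df_den`, `gg_epsilon`, `p_uncorrected`, `p_gg`.
#' @export
rm_anova_twoway <- function(Y, names_a = NULL, names_b = NULL) {
  d <- dim(Y)
  if (length(d) != 3L)
    mf_stop("mf_design_error", "Y must be a subjects x A x B array")
  n <- d[1]; a <- d[2]; b <- d[3]
  if (n < 2L || a < 2L || b < 2L)
    mf_stop("mf_design_error", "need >= 2 subjects and >= 2 levels per factor")
  grand <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_sab <- ss_total - ss_a - ss_b - ss_s - ss_sa - ss_sb - ss_ab

  Ca <- orth_contrasts(a)
  Cb <- orth_contrasts(b)
  ones_a <- matrix(1 / sqrt(a), 1, a)
  ones_b <- matrix(1 / sqrt(b), 1, b)
  # subject x cell matrix, cells ordered (A fastest within B)
  flat <- matrix(Y, nrow = n)
  eff <- function(label, ss_eff, df1, ss_err, df2, C) {
    Fv <- f_ratio(ss_eff, df1, ss_err, df2, 1e-12 * (ss_total + 1))
    eps <- gg_epsilon(flat, C)
    data.frame(effect = label, F = Fv, df_num = df1, df_den = df2,
               gg_epsilon = eps, p_uncorrected = pf_upper(Fv, df1, df2),
               p_gg = pf_upper(Fv, eps * df1, eps * df2),
               stringsAsFactors = FALSE)
  }
  # cells are (i_a + a * i_b): kronecker(Cb, Ca) picks the right slots
  out <- rbind(
    eff("A", ss_a, a - 1, ss_sa, (a - 1) * (n - 1), kronecker(ones_b, Ca)),
    eff("B", ss_b, b - 1, ss_sb, (b - 1) * (n - 1), kronecker(Cb, ones_a)),
    eff("A:B", ss_ab, (a - 1) * (b - 1), ss_sab, (a - 1) * (b - 1) * (n - 1),
        kronecker(Cb, Ca)))
  if (!is.null(names_a)) attr(out, "names_a") <- names_a
  if (!is.null(names_b)) attr(out, "names_b") <- names_b
  out
}

#' Simple main effects of factor A at each level of factor B
#'
#' After a significant interaction: at each level of B (e.g. each
#' threshold), all pairwise paired comparisons between the levels of A
#' (e.g. modalities), Sidak-corrected within the level's family.
#'
#' @param Y 3-D array `n_subjects x a x b` as in [rm_anova_twoway()].
#' @param names_a,names_b level labels.
#' @param at optional subset of B levels (labels or indices).
#' @return data.frame shaped like a simple-main-effects table: one row
#'   per B level and A pair with mean difference, SE and adjusted p.
#' @export
simple_main_effects <- function(Y, names_a = NULL, names_b = NULL,
                                at = NULL) {
  d <- dim(Y)
  if (length(d) != 3L)
    mf_stop("mf_design_error", "Y must be a subjects x A x B array")
  if (is.null(names_a)) names_a <- paste0("A", seq_len(d[2]))
  if (is.null(names_b)) names_b <- paste0("B", seq_len(d[3]))
  idx <- seq_len(d[3])
  if (!is.null(at)) {
    idx <- if (is.character(at)) match(at, names_b) else as.integer(at)
    if (anyNA(idx) || any(idx < 1L | idx > d[3]))
      mf_stop("mf_unknown_level", "unknown factor-B level in 'at'")
  }
  out <- lapply(idx, function(j) {
    slab <- Y[, , j, drop = TRUE]
    colnames(slab) <- names_a
    pw <- pairwise_paired(slab)
    cbind(data.frame(level = names_b[j], stringsAsFactors = FALSE), pw)
  })
  do.call(rbind, out)
}

#' Repeatability over repeated scans of one object
#'
#' Every ordered pair of the `n` meshes (`n * (n - 1)` pairs; 10 scans
#' give 90) is registered and summarized, each mesh in turn serving as
#' the reference. Returns the mean of the per-pair mean deviations
#' (accuracy-style figure) and the mean of the per-pair SDs (the
#' repeatability figure).
#'
#' @param meshes list of >= 2 [tri_mesh()] objects of the same object.
#' @param cfg an [icp_config()].
#' @param register set `FALSE` if the meshes are already co-registered.
#' @return list with `mean_diff_mm`, `mean_sd_mm`, `n_pairs`, and the
#'   per-pair data.frame `pairs`.
#' @export
repeatability <- function(meshes, cfg = icp_config(n_sample_pairs = 5000L),
                          register = TRUE) {
  n <- length(meshes)
  if (n < 2L)
    mf_stop("mf_design_error", "repeatability needs >= 2 meshes")
  trees <- lapply(meshes, surface_tree)
  rows <- list()
  pair_i <- 0L
  for (j in seq_len(n)) {      # j = reference
    for (i in seq_len(n)) {
      if (i == j) next
      pair_i <- pair_i + 1L
      m <- meshes[[i]]
      if (register) {
        cfg_i <- cfg
        cfg_i$rng_seed <- cfg$rng_seed + pair_i
        reg <- icp_register(m, meshes[[j]], cfg_i, fixed_tree = trees[[j]])
        m <- rt_apply_mesh(reg$transform, m)
      }
      dvs <- face_deviations(m, trees[[j]])
      rows[[pair_i]] <- data.frame(test = i, reference = j,
                                   mean_mm = mean(dvs),
                                   sd_mm = if (length(dvs) > 1) sd(dvs) else 0)
    }
  }
  pairs <- do.call(rbind, rows)
  list(mean_diff_mm = mean(pairs$mean_mm), mean_sd_mm = mean(pairs$sd_mm),
       n_pairs = nrow(pairs), pairs = pairs)
}
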