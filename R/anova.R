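#' Degrees of freedom of the seed-by-target interaction
#'
#' For a two-way fully within-subject design with `a` seed levels, `b`
#' target levels and `n` subjects, the unadjusted interaction F test has
#' `df1 = (a - 1)(b - 1)` and `df2 = (a - 1)(b - 1)(n - 1)`.
#'
#' @param a,b,n factor level counts (>= 2) and subject count (>= 2).
#' @return Named integer vector `c(df1, df2)`.
#' @export
interaction_dof <- function(a, b, n) {
  stopifnot(a >= 2, b >= 2, n >= 2)
  c(df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1))
}

#' Two-way fully within-subject repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a subjects x A x B data array
#' (here: subjects x seeds x targets of functional-connectivity values).
#' Each effect is tested against its own interaction-with-subject error
#' term; the seed-by-target interaction F is `MS_AB / MS_ABxSubject`.
#' Sphericity of the interaction contrasts is quantified by the
#' Greenhouse-Geisser epsilon, computed from the covariance of the
#' orthonormal interaction contrast scores, and the less conservative
#' Huynh-Feldt epsilon
#' `((n (k-1) e_GG - 2) / ((k-1) (n - 1 - (k-1) e_GG))` with
#' `k - 1 = (a-1)(b-1)`, capped at 1. Both the unadjusted p-value and the
#' Huynh-Feldt-adjusted p-value (F referred to epsilon-scaled degrees of
#' freedom) are always reported; the printed summary flags solutions with
#' `e_HF < 0.75` where the adjustment matters.
#'
#' Input may also be a long data.frame with columns `subject`, `seed`,
#' `target`, `value`; subjects with any missing cell are dropped listwise
#' with a message.
#'
#' @param data numeric array `n x a x b`, or a long data.frame.
#' @return Object of class `rm_anova`: `table` (SS/df/MS/F/p for A, B, AxB
#'   and their error strata), `F_interaction`, `df1`, `df2`, `epsilon_gg`,
#'   `epsilon_hf`, `df1_adj`, `df2_adj`, `p_unadjusted`, `p_adjusted`,
#'   `n`, `a`, `b`.
#' @export
two_way_rm_anova <- function(data) {
  if (is.data.frame(data)) data <- long_to_array(data)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a subjects x A x B array")
  if (anyNA(data)) {
    keep <- apply(data, 1L, function(s) !anyNA(s))
    message(sprintf("dropping %d subject(s) with missing cells",
                    sum(!keep)))
    data <- data[keep, , , drop = FALSE]
  }
  n <- dim(data)[1L]; a <- dim(data)[2L]; b <- dim(data)[3L]
  if (n < 2L || a < 2L || b < 2L)
    stopf("need n >= 2 subjects and >= 2 levels per factor (got %d, %d, %d)",
          n, a, b)
  g <- mean(data)
  m_a <- apply(data, 2L, mean)
  m_b <- apply(data, 3L, mean)
  m_s <- apply(data, 1L, mean)
  m_ab <- apply(data, c(2L, 3L), mean)
  m_sa <- apply(data, c(1L, 2L), mean)
  m_sb <- apply(data, c(1L, 3L), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + g)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + g)^2)
  ss_tot <- sum((data - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  dfs <- c(A = a - 1, `A:S` = (a - 1) * (n - 1),
           B = b - 1, `B:S` = (b - 1) * (n - 1),
           `A:B` = (a - 1) * (b - 1),
           `A:B:S` = (a - 1) * (b - 1) * (n - 1),
           S = n - 1)
  sss <- c(A = ss_a, `A:S` = ss_as, B = ss_b, `B:S` = ss_bs, `A:B` = ss_ab,
           `A:B:S` = ss_abs, S = ss_s)
  mss <- sss / dfs
  if (mss[["A:B:S"]] <= 0)
    stopf("degenerate data: zero interaction error mean square")
  f_int <- mss[["A:B"]] / mss[["A:B:S"]]
  df1 <- dfs[["A:B"]]; df2 <- dfs[["A:B:S"]]
  p_un <- stats::pf(f_int, df1, df2, lower.tail = FALSE)

  k1 <- (a - 1) * (b - 1)
  if (n > k1) {
    eps <- interaction_epsilons(data, n, a, b)
  } else {
    warnf(paste0("n (%d) <= (a-1)(b-1) (%d): sphericity epsilons not ",
                 "estimable; reporting unadjusted p"), n, k1)
    eps <- list(gg = NA_real_, hf = NA_real_)
  }
  if (is.na(eps$hf)) {
    df1_adj <- df2_adj <- NA_real_
    p_adj <- p_un
  } else {
    df1_adj <- eps$hf * df1
    df2_adj <- eps$hf * df2
    p_adj <- stats::pf(f_int, df1_adj, df2_adj, lower.tail = FALSE)
  }
  fvals <- c(mss[["A"]] / mss[["A:S"]], NA, mss[["B"]] / mss[["B:S"]], NA,
             f_int, NA, NA)
  pvals <- c(stats::pf(fvals[1L], dfs[["A"]], dfs[["A:S"]],
                       lower.tail = FALSE), NA,
             stats::pf(fvals[3L], dfs[["B"]], dfs[["B:S"]],
                       lower.tail = FALSE), NA, p_un, NA, NA)
  tab <- data.frame(effect = names(dfs), SS = unname(sss), df = unname(dfs),
                    MS = unname(mss), F = unname(fvals), p = unname(pvals),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, F_interaction = unname(f_int), df1 = df1,
                 df2 = df2, epsilon_gg = eps$gg, epsilon_hf = eps$hf,
                 df1_adj = df1_adj, df2_adj = df2_adj, p_unadjusted = p_un,
                 p_adjusted = p_adj, n = n, a = a, b = b),
            class = "rm_anova")
}

# Greenhouse-Geisser and Huynh-Feldt epsilons from the doubly-centred
# covariance of the orthonormal interaction contrast scores.
interaction_epsilons <- function(data, n, a, b) {
  Ca <- orthonormal_contrasts(a)
  Cb <- orthonormal_contrasts(b)
  k1 <- (a - 1) * (b - 1)
  scores <- vapply(seq_len(n), function(s)
    as.vector(t(Ca) %*% data[s, , ] %*% Cb), numeric(k1))
  scores <- if (k1 == 1L) matrix(scores, ncol = 1L) else t(scores)
  S <- stats::cov(scores)
  gg <- sum(diag(S))^2 / (k1 * sum(S * S))
  gg <- min(1, max(1 / k1, gg))
  hf <- (n * k1 * gg - 2) / (k1 * (n - 1 - k1 * gg))
  hf <- min(1, max(hf, gg))
  list(gg = gg, hf = hf)
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), "/")
}

long_to_array <- function(df) {
  need <- c("subject", "seed", "target", "value")
  if (!all(need %in% names(df)))
    stopf("long data needs columns %s", paste(need, collapse = ", "))
  subj <- sort(unique(df$subject))
  aa <- sort(unique(df$seed))
  bb <- sort(unique(df$target))
  arr <- array(NA_real_, dim = c(length(subj), length(aa), length(bb)))
  arr[cbind(match(df$subject, subj), match(df$seed, aa),
            match(df$target, bb))] <- df$value
  arr
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (n = %d, %d x %d levels)\n",
              x$n, x$a, x$b))
  cat(sprintf("Interaction: F(%g, %g) = %.3f, p = %.3g (unadjusted)\n",
              x$df1, x$df2, x$F_interaction, x$p_unadjusted))
  if (!is.na(x$epsilon_hf)) {
    cat(sprintf(
      "Huynh-Feldt: eps_GG = %.3f, eps_HF = %.3f, F(%.1f, %.1f), p = %.3g%s\n",
      x$epsilon_gg, x$epsilon_hf, x$df1_adj, x$df2_adj, x$p_adjusted,
      if (x$epsilon_hf < 0.75) "  [sphericity doubtful: adjustment matters]"
      else ""))
  }
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, ...) {
  print(object)
  cat("\n")
  tab <- object$table
  tab[c("SS", "MS", "F", "p")] <- lapply(tab[c("SS", "MS", "F", "p")],
                                         signif, 5)
  print(tab, row.names = FALSE)
  invisible(object$table)
}
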