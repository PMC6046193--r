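#' Paired t test
#'
#' Thin wrapper around [stats::t.test()] (paired, two-sided) returning the
#' fields the pipeline reports. Zero-variance differences are flagged rather
#' than erroring.
#'
#' @param a,b Paired per-participant values (equal length >= 2).
#' @return A `paired_result` list: `mean_diff`, `se`, `ci95` (length 2),
#'   `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    out <- list(mean_diff = mean(d), se = 0, ci95 = c(mean(d), mean(d)),
                t_stat = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                degenerate = TRUE)
    class(out) <- "paired_result"
    return(out)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  out <- list(mean_diff = unname(tt$estimate),
              se = unname(tt$stderr),
              ci95 = as.numeric(tt$conf.int),
              t_stat = unname(tt$statistic),
              df = unname(tt$parameter),
              p_value = tt$p.value,
              degenerate = FALSE)
  class(out) <- "paired_result"
  out
}

# Orthonormal contrast matrix for a factor with l levels:
# (l-1) rows, each orthogonal to the constant vector and mutually orthonormal.
orthonormal_contrasts <- function(l) {
  if (l < 2) stop("factor needs >= 2 levels", call. = FALSE)
  q <- qr.Q(qr(cbind(rep(1, l), stats::contr.helmert(l))))
  t(q[, -1, drop = FALSE])
}

#' Fully within-subject repeated-measures ANOVA
#'
#' Decomposes a complete balanced within-subject design into all main effects
#' and interactions. For each effect the subject x cell matrix is projected
#' onto an orthonormal contrast basis (the Kronecker product of per-factor
#' contrasts and equal-weight averaging vectors); the effect sum of squares
#' comes from the projected means, the error term from the subject-by-effect
#' interaction, Greenhouse-Geisser epsilon from the covariance of the
#' projected scores, and partial eta squared as
#' `SS_effect / (SS_effect + SS_error)`. Effects with more than one
#' numerator df additionally report the Greenhouse-Geisser corrected p value
#' (for single-df effects sphericity holds trivially and `epsilon = 1`).
#'
#' @param data Long-format data frame, one row per subject x cell (rows within
#'   a subject x cell are averaged first).
#' @param dv Name of the numeric dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject-identifier column.
#' @return An `anova_result` data frame, one row per effect: `effect`,
#'   `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`, `p`, `gg_epsilon`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`, `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv, within, subject = "participant_id") {
  stopifnot(is.data.frame(data), dv %in% names(data),
            all(within %in% names(data)), subject %in% names(data))
  agg <- stats::aggregate(data[dv], by = data[c(subject, within)], FUN = mean)
  levels_list <- lapply(within, function(f) sort(unique(as.character(agg[[f]]))))
  names(levels_list) <- within
  n_cells <- prod(vapply(levels_list, length, integer(1)))
  subjects <- sort(unique(as.character(agg[[subject]])))
  n <- length(subjects)
  if (n < 2) stop("rm_anova: need >= 2 subjects", call. = FALSE)

  # cell grid with the first factor varying fastest (kronecker order below)
  grid <- expand.grid(levels_list, stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(grid[within], sep = "\r"))
  agg_key <- do.call(paste, c(lapply(within, function(f) as.character(agg[[f]])),
                              sep = "\r"))
  Y <- matrix(NA_real_, nrow = n, ncol = n_cells,
              dimnames = list(subjects, cell_key))
  Y[cbind(as.character(agg[[subject]]), agg_key)] <- agg[[dv]]
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)
    stop("rm_anova: unbalanced design; missing cells: ",
         paste(paste(rownames(Y)[bad[, 1]], colnames(Y)[bad[, 2]], sep = " / "),
               collapse = "; "),
         call. = FALSE)
  }

  contrasts <- lapply(levels_list, function(lv) orthonormal_contrasts(length(lv)))
  means_vec <- lapply(levels_list, function(lv) {
    matrix(1 / sqrt(length(lv)), nrow = 1, ncol = length(lv))
  })

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    mats <- lapply(within, function(f) {
      if (f %in% eff) contrasts[[f]] else means_vec[[f]]
    })
    M <- Reduce(kronecker, rev(mats))  # first factor varies fastest
    Z <- Y %*% t(M)
    q <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    resid <- sweep(Z, 2, zbar)
    ss_err <- sum(resid^2)
    df1 <- q
    df2 <- q * (n - 1)
    # degenerate data (dv constant over cells): both SS vanish, report F = 0
    if (ss_eff + ss_err < 1e-9 * max(1, sum(Y^2) / length(Y))) {
      ss_eff <- 0
      ss_err <- 0
    }
    Fval <- if (ss_eff == 0) 0 else (ss_eff / df1) / (ss_err / df2)
    if (q > 1) {
      S <- stats::cov(Z)
      eps <- sum(diag(S))^2 / (q * sum(S * S))
    } else {
      eps <- 1
    }
    data.frame(effect = paste(eff, collapse = ":"),
               df_num = df1, df_den = df2,
               ss_effect = ss_eff, ss_error = ss_err,
               F = Fval,
               p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
               gg_epsilon = eps,
               df_num_gg = df1 * eps, df_den_gg = df2 * eps,
               p_gg = stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE),
               partial_eta_sq = if (ss_eff == 0) 0 else ss_eff / (ss_eff + ss_err))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' All pairwise paired t tests among the cells of a (possibly crossed) factor
#' family, with p values adjusted by the family size `m`
#' (`p_adj = min(1, p * m)` via [stats::p.adjust()] semantics on the declared
#' family).
#'
#' @param data Long-format data frame, one row per subject x cell.
#' @param dv Dependent-variable column name.
#' @param cells Character vector of factor columns whose crossed levels form
#'   the comparison family.
#' @param subject Subject-identifier column name.
#' @return Data frame, one row per comparison: `cell_a`, `cell_b`,
#'   `mean_diff`, `t_stat`, `df`, `p`, `p_bonferroni`, `m`.
#' @export
bonferroni_pairwise <- function(data, dv, cells, subject = "participant_id") {
  agg <- stats::aggregate(data[dv], by = data[c(subject, cells)], FUN = mean)
  agg$cell <- do.call(paste, c(lapply(cells, function(f) as.character(agg[[f]])),
                               sep = "."))
  labs <- sort(unique(agg$cell))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    sa <- agg[agg$cell == pr[1], c(subject, dv)]
    sb <- agg[agg$cell == pr[2], c(subject, dv)]
    merged <- merge(sa, sb, by = subject, suffixes = c("_a", "_b"))
    res <- paired_t(merged[[paste0(dv, "_a")]], merged[[paste0(dv, "_b")]])
    data.frame(cell_a = pr[1], cell_b = pr[2],
               mean_diff = res$mean_diff, t_stat = res$t_stat,
               df = res$df, p = res$p_value, m = m)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  rownames(out) <- NULL
  out[, c("cell_a", "cell_b", "mean_diff", "t_stat", "df", "p",
          "p_bonferroni", "m")]
}
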