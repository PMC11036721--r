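#' Blind method-of-moments dispersion with a robust parametric trend
#'
#' With one pooled library per timepoint there are no replicates, so the NB
#' dispersion is estimated "blind": per gene, the method-of-moments estimator
#' alpha_hat = (s^2 - mu) / mu^2 on size-factor-normalized counts across all
#' timepoints, then a parametric trend alpha(mu) = a0/mu + a1 fitted by robust
#' regression ([MASS::rlm()]) over genes with positive mean. Because the
#' per-gene across-time variance of a genuinely changing gene is dominated by
#' its signal, the default working dispersion is the trend value (a fit-only
#' sharing mode); `sharing = "max"` instead takes max(alpha_hat, trend), which
#' is more conservative but has essentially no power against transient
#' changes, since the change itself inflates alpha_hat.
#'
#' @param counts matrix or [count_matrix()], genes x samples (>= 3 samples).
#' @param sf size factors (default [size_factors()]).
#' @param sharing `"trend"` (default) or `"max"`.
#' @return a `DispersionModel`: list with per-gene `alpha_mom`, trend
#'   coefficients `a0`, `a1`, per-gene `working` dispersion and the `sharing`
#'   mode.
#' @export
fit_dispersion_blind <- function(counts, sf = NULL,
                                 sharing = c("trend", "max")) {
  sharing <- match.arg(sharing)
  m <- get_counts(counts)
  if (ncol(m) < 3) abort("dispersion is unidentifiable with < 3 samples")
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  pos <- mu > 0
  raw <- rep(NA_real_, nrow(m))
  raw[pos] <- (s2[pos] - mu[pos]) / mu[pos]^2   # unclamped, for the fit
  alpha_mom <- pmax(0, raw)
  alpha_mom[!pos] <- 0
  fit_ok <- pos & is.finite(raw)
  if (sum(fit_ok) < 10)
    abort("too few genes with positive mean to fit a dispersion trend")
  fit <- suppressWarnings(
    MASS::rlm(raw[fit_ok] ~ I(1 / mu[fit_ok]), maxit = 50))
  a1 <- max(0, unname(stats::coef(fit)[1]))
  a0 <- max(0, unname(stats::coef(fit)[2]))
  trend <- rep(0, nrow(m))
  trend[pos] <- pmax(1e-8, a0 / mu[pos] + a1)
  working <- if (sharing == "max") pmax(alpha_mom, trend) else trend
  names(working) <- names(alpha_mom) <- rownames(m)
  structure(list(alpha_mom = alpha_mom, a0 = a0, a1 = a1,
                 trend = stats::setNames(trend, rownames(m)),
                 working = working, sharing = sharing),
            class = "DispersionModel")
}

# Two-sided NB exact test for one gene between two single libraries.
# Conditions on the rounded normalized sum s = a + b: under the null both
# samples are NB with mean s/2 and the given dispersion, and the p-value is
# the total conditional probability of all splits (x, s - x) no more likely
# than the observed one (ties included). alpha = 0 reduces to the Poisson
# case, i.e. a Binomial(s, 1/2) split.
nb_exact_test <- function(a, b, alpha) {
  s <- a + b
  if (s == 0) return(1)
  if (s > 1e6) {
    # beta-binomial (NB) / binomial (Poisson) conditional is effectively
    # normal at this depth; avoids allocating the full 0:s support
    v <- if (alpha > 0) (s / 4) * (s + 2 / alpha) / (1 + 2 / alpha) else s / 4
    return(min(1, 2 * stats::pnorm(-abs(a - s / 2) / sqrt(v))))
  }
  mu <- s / 2
  dens <- if (alpha > 0) stats::dnbinom(0:s, mu = mu, size = 1 / alpha)
          else stats::dpois(0:s, mu)
  joint <- dens * rev(dens)
  p_obs <- joint[a + 1]
  min(1, sum(joint[joint <= p_obs * (1 + 1e-8)]) / sum(joint))
}

#' Differential expression between two adjacent timepoints
#'
#' For each gene, the log2 fold change is computed on size-factor-normalized
#' counts with a pseudocount (later vs earlier), and a two-sided p-value from
#' a no-replicate NB exact test conditioning on the rounded normalized sum.
#' Status follows the DEG rule: U if log2fc > 1 and p < 0.05, D if
#' log2fc < -1 and p < 0.05, M otherwise.
#'
#' @param counts matrix or [count_matrix()].
#' @param sf size factors.
#' @param model a `DispersionModel` from [fit_dispersion_blind()].
#' @param t index of the earlier timepoint; the interval is `t` vs `t + 1`.
#' @param pseudocount added to normalized counts in the fold change
#'   (default 1).
#' @param lfc_cutoff,p_cutoff DEG thresholds (defaults 1 and 0.05).
#' @return data.frame of `DERecord`s: gene, interval, log2fc, p_value, status.
#' @export
test_adjacent <- function(counts, sf, model, t, pseudocount = 1,
                          lfc_cutoff = 1, p_cutoff = 0.05) {
  m <- get_counts(counts)
  if (t < 1 || t >= ncol(m))
    abort("t must index two chronologically adjacent samples (1..%d)",
          ncol(m) - 1)
  norm <- sweep(m[, c(t, t + 1), drop = FALSE], 2, sf[c(t, t + 1)], "/")
  lfc <- log2((norm[, 2] + pseudocount) / (norm[, 1] + pseudocount))
  a <- round(norm[, 1]); b <- round(norm[, 2])
  alpha <- model$working[rownames(m)]
  p <- vapply(seq_len(nrow(m)),
              function(i) nb_exact_test(a[i], b[i], alpha[i]), numeric(1))
  status <- rep("M", nrow(m))
  status[lfc > lfc_cutoff & p < p_cutoff] <- "U"
  status[lfc < -lfc_cutoff & p < p_cutoff] <- "D"
  interval <- interval_labels(colnames(m))[t]
  data.frame(gene = rownames(m), interval = interval, log2fc = unname(lfc),
             p_value = p, status = status, stringsAsFactors = FALSE)
}

#' Differential expression across all adjacent intervals
#'
#' Convenience wrapper: estimates size factors and a blind dispersion model
#' when not supplied, then runs [test_adjacent()] for every adjacent pair.
#'
#' @inheritParams test_adjacent
#' @param model optional `DispersionModel`; fitted when `NULL`.
#' @param sf optional size factors; estimated when `NULL`.
#' @return stacked data.frame of `DERecord`s with `interval` as a factor in
#'   chronological order.
#' @export
de_adjacent <- function(counts, sf = NULL, model = NULL, pseudocount = 1,
                        lfc_cutoff = 1, p_cutoff = 0.05) {
  m <- get_counts(counts)
  if (is.null(sf)) sf <- size_factors(m)
  if (is.null(model)) model <- fit_dispersion_blind(m, sf)
  recs <- lapply(seq_len(ncol(m) - 1), function(t)
    test_adjacent(m, sf, model, t, pseudocount, lfc_cutoff, p_cutoff))
  out <- do.call(rbind, recs)
  out$interval <- factor(out$interval, levels = interval_labels(colnames(m)))
  out
}

#' Per-interval DEG tally
#'
#' @param records data.frame of `DERecord`s (possibly several RNA classes
#'   stacked; add a `class` column to get per-class rows).
#' @return list with `by_interval` (interval, up, down, total) and
#'   `grand_total`; up + down = total per interval by construction.
#' @export
deg_table <- function(records) {
  if (nrow(records) == 0)
    return(list(by_interval = data.frame(interval = character(0),
                                         up = integer(0), down = integer(0),
                                         total = integer(0)),
                grand_total = 0L))
  lv <- if (is.factor(records$interval)) levels(records$interval)
        else unique(records$interval)
  up <- tapply(records$status == "U", records$interval, sum)[lv]
  down <- tapply(records$status == "D", records$interval, sum)[lv]
  up[is.na(up)] <- 0; down[is.na(down)] <- 0
  by_int <- data.frame(interval = lv, up = as.integer(up),
                       down = as.integer(down),
                       total = as.integer(up + down), row.names = NULL)
  list(by_interval = by_int, grand_total = sum(by_int$total))
}
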