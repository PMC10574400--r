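#' Rank genes by circadian oscillation correlation
#'
#' Genes are sorted by correlation in descending order (larger correlation
#' means better oscillation); ties are broken deterministically by gene id.
#' Non-converged or correlation-NA genes are dropped by default, or kept at
#' the bottom with score -1.
#'
#' @param fits a fits table from [fit_all()].
#' @param non_converged `"drop"` or `"floor"` (assign score -1).
#' @return object of class `ranked_list`: data.frame `gene`, `score`,
#'   strictly ordered.
#' @export
build_ranked_list <- function(fits, non_converged = c("drop", "floor")) {
  non_converged <- match.arg(non_converged)
  .check(nrow(fits) > 0, "empty fits table")
  .check(!anyDuplicated(fits$gene), "duplicate gene ids")
  score <- ifelse(fits$converged & !is.na(fits$correlation),
                  fits$correlation, NA_real_)
  if (non_converged == "drop") {
    keep <- !is.na(score)
    fits <- fits[keep, , drop = FALSE]
    score <- score[keep]
  } else {
    score[is.na(score)] <- -1
  }
  .check(length(score) > 0, "no ranked genes left")
  o <- order(-score, fits$gene)
  structure(data.frame(gene = fits$gene[o], score = score[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score of one gene set
#'
#' Walking down the ranked list, hits increment the running sum by
#' `|score|^p` normalized by the set's total hit weight, misses decrement
#' by `1/(N - n)`; the enrichment score is the extreme deviation of the
#' running sum from zero. A set concentrated at the top of the list gets a
#' positive ES, at the bottom a negative ES. If all hit weights are zero
#' the hits fall back to equal weights.
#'
#' @param ranked a [build_ranked_list()] object.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent hit-weight exponent p (default 1).
#' @return list with `es`, `running` (the full running sum), `peak_rank`
#'   (rank index at which |running| peaks), `size` (set size after
#'   intersection with the ranked universe).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  n <- sum(hit)
  .check(n > 0, "gene set has empty intersection with the ranked list")
  .check(n < N, "gene set covers the whole universe")
  w <- abs(ranked$score)^weight_exponent
  w[!hit] <- 0
  NR <- sum(w)
  if (NR == 0) {
    w[hit] <- 1
    NR <- n
  }
  inc <- ifelse(hit, w / NR, -1 / (N - n))
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak_rank = peak, size = n)
}

# internal: ES from sorted hit positions only, O(set size); identical to
# the extreme of the running sum in enrichment_score()
.es_from_positions <- function(pos, wts, N) {
  o <- order(pos)
  pos <- pos[o]; wts <- wts[o]
  n <- length(pos)
  NR <- sum(wts)
  if (NR == 0) { wts <- rep(1, n); NR <- n }
  cw <- cumsum(wts) / NR
  miss <- (pos - seq_len(n)) / (N - n)
  hi <- max(cw - miss)            # running sum at each hit
  lo <- min(c(0, cw[-n]) - miss)  # just before each hit (cw_{i-1})
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Permutation normalization of enrichment scores
#'
#' Null distributions are built by gene-label permutation: for each
#' distinct set size, random sets of that size are drawn from the ranked
#' universe. NES = ES divided by the mean |null ES| of matching sign; the
#' two-tail empirical p is `(1 + #(|null ES| >= |ES|)) / (1 + n_perm)`
#' (add-one corrected, so its floor is `1/(n_perm + 1)`); FDR follows the
#' positive/negative pooled-null convention of preranked GSEA. Fully
#' reproducible for a given seed.
#'
#' @param es_table data.frame with columns `set`, `es`, `size` (e.g. built
#'   by [run_enrichment()] internals).
#' @param ranked the [build_ranked_list()] used for the scores.
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer seed (mandatory; no default randomness).
#' @param weight_exponent hit-weight exponent, matching the ES computation.
#' @return `es_table` with `nes`, `pval`, `fdr` columns appended; sets with
#'   a degenerate null get NA NES and a warning.
#' @export
normalize_and_test <- function(es_table, ranked, n_permutations = 1000,
                               seed, weight_exponent = 1) {
  .check(n_permutations >= 100, "need at least 100 permutations")
  .check(!missing(seed), "seed is mandatory")
  N <- nrow(ranked)
  wabs <- abs(ranked$score)^weight_exponent
  set.seed(seed)
  sizes <- sort(unique(es_table$size))
  null_es <- lapply(sizes, function(s) {
    vapply(seq_len(n_permutations), function(i) {
      pos <- sample.int(N, s)
      .es_from_positions(pos, wabs[pos], N)
    }, numeric(1))
  })
  names(null_es) <- as.character(sizes)

  nes <- pval <- numeric(nrow(es_table))
  null_nes_pool <- list()
  for (i in seq_len(nrow(es_table))) {
    es <- es_table$es[i]
    nul <- null_es[[as.character(es_table$size[i])]]
    same <- nul[sign(nul) == sign(es)]
    if (length(same) == 0 || mean(abs(same)) == 0) {
      warning(sprintf("degenerate null for set '%s'", es_table$set[i]))
      nes[i] <- NA_real_; pval[i] <- NA_real_
      next
    }
    nes[i] <- es / mean(abs(same))
    pval[i] <- (1 + sum(abs(nul) >= abs(es))) / (1 + length(nul))
  }
  # pooled null NES for the FDR (each null ES normalized within its size)
  pool <- unlist(lapply(sizes, function(s) {
    nul <- null_es[[as.character(s)]]
    pos_m <- mean(abs(nul[nul > 0])); neg_m <- mean(abs(nul[nul < 0]))
    out <- numeric(0)
    if (is.finite(pos_m) && pos_m > 0) out <- c(out, nul[nul > 0] / pos_m)
    if (is.finite(neg_m) && neg_m > 0) out <- c(out, nul[nul < 0] / neg_m)
    out
  }))
  fdr <- rep(NA_real_, length(nes))
  for (i in seq_along(nes)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- mean(pool[pool > 0] >= nes[i])
      den <- mean(nes[!is.na(nes) & nes > 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    fdr[i] <- if (is.finite(num / den)) min(num / den, 1) else NA_real_
  }
  es_table$nes <- nes
  es_table$pval <- pval
  es_table$fdr <- fdr
  es_table
}

#' Correlation-ranked gene-set enrichment analysis
#'
#' Runs the full preranked analysis: builds the descending
#' oscillation-correlation ranking, computes the weighted KS enrichment
#' score for every gene set whose intersection with the universe has size
#' within `[min_size, max_size]` (defaults 3 and 800), and normalizes and
#' tests by gene-label permutation. Sets with empty intersection are
#' skipped with a message.
#'
#' @param fits a fits table (or a prebuilt `ranked_list`).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param min_size,max_size set-size bounds after intersection.
#' @param n_permutations permutations for the null (default 1000).
#' @param seed integer seed (mandatory).
#' @param weight_exponent hit-weight exponent (default 1).
#' @return data.frame of class `enrichment_result`: `set`, `description`,
#'   `size`, `es`, `peak_rank`, `nes`, `pval`, `fdr`.
#' @export
run_enrichment <- function(fits, gene_sets, min_size = 3, max_size = 800,
                           n_permutations = 1000, seed, weight_exponent = 1) {
  .check(!missing(seed), "seed is mandatory")
  ranked <- if (inherits(fits, "ranked_list")) fits else
    build_ranked_list(fits)
  descr <- attr(gene_sets, "descriptions")
  if (is.null(descr)) {
    descr <- stats::setNames(rep(NA_character_, length(gene_sets)),
                             names(gene_sets))
  }
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene %in% s), integer(1))
  skipped <- names(gene_sets)[sizes == 0]
  if (length(skipped) > 0) {
    message(sprintf("%d set(s) skipped: empty intersection", length(skipped)))
  }
  keep <- sizes >= min_size & sizes <= pmin(max_size, nrow(ranked) - 1)
  .check(any(keep), "no gene set within the size bounds")
  rows <- lapply(names(gene_sets)[keep], function(nm) {
    e <- enrichment_score(ranked, gene_sets[[nm]], weight_exponent)
    data.frame(set = nm, description = unname(descr[nm]), size = e$size,
               es = e$es, peak_rank = e$peak_rank, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- normalize_and_test(tab, ranked, n_permutations, seed,
                            weight_exponent)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cross-source NES quadrant comparison
#'
#' Intersects the gene sets surviving the chosen threshold in both sources
#' and labels each by the signs of its two NES values: `++` (top of both
#' lists), `--`, and the off-diagonal `+-` / `-+` quadrants where circadian
#' enrichment disagrees between the sources. Off-diagonal sets are sorted
#' by ascending combined p (`max(p_a, p_b)`).
#'
#' @param res_a,res_b `enrichment_result` tables sharing a set-id namespace.
#' @param threshold_mode `"p"`, `"fdr"` (<= alpha in both sources) or
#'   `"none"`.
#' @param alpha significance threshold (default 0.05).
#' @return list with `table` (per common set: `set`, `nes_a`, `nes_b`,
#'   `p_a`, `p_b`, `combined_p`, `quadrant`) and `counts`
#'   (`n_a`, `n_b`, `a_only`, `b_only`, `common`). An empty intersection
#'   gives an empty table, not an error.
#' @export
quadrant_compare <- function(res_a, res_b,
                             threshold_mode = c("p", "fdr", "none"),
                             alpha = 0.05) {
  threshold_mode <- match.arg(threshold_mode)
  pass <- function(res) {
    ok <- !is.na(res$nes)
    if (threshold_mode == "p") ok <- ok & res$pval <= alpha
    if (threshold_mode == "fdr") ok <- ok & res$fdr <= alpha
    res[ok, , drop = FALSE]
  }
  a <- pass(res_a); b <- pass(res_b)
  common <- intersect(a$set, b$set)
  ia <- match(common, a$set); ib <- match(common, b$set)
  tab <- data.frame(set = common,
                    nes_a = a$nes[ia], nes_b = b$nes[ib],
                    p_a = a$pval[ia], p_b = b$pval[ib],
                    stringsAsFactors = FALSE)
  tab$combined_p <- pmax(tab$p_a, tab$p_b)
  tab$quadrant <- paste0(ifelse(tab$nes_a >= 0, "+", "-"),
                         ifelse(tab$nes_b >= 0, "+", "-"))
  off <- tab$quadrant %in% c("+-", "-+")
  tab <- rbind(tab[!off, , drop = FALSE],
               tab[off, , drop = FALSE][order(tab$combined_p[off]), ,
                                        drop = FALSE])
  rownames(tab) <- NULL
  list(table = tab,
       counts = c(n_a = nrow(a), n_b = nrow(b),
                  a_only = nrow(a) - length(common),
                  b_only = nrow(b) - length(common),
                  common = length(common)))
}

#' Correlation of NES values between two sources
#'
#' Pearson correlation of the common sets' NES values, with the F-test
#' p-value of the simple linear regression of source-B NES on source-A NES.
#'
#' @param quadrant_table the `table` element of [quadrant_compare()]
#'   (>= 3 common sets, non-constant NES).
#' @return list with `r`, `p_value`, `n`.
#' @export
nes_correlation <- function(quadrant_table) {
  .check(nrow(quadrant_table) >= 3, "need at least 3 common sets")
  x <- quadrant_table$nes_a; y <- quadrant_table$nes_b
  .check(stats::sd(x) > 0 && stats::sd(y) > 0, "constant NES vector")
  fit <- stats::lm(y ~ x)
  fs <- summary(fit)$fstatistic
  list(r = stats::cor(x, y),
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = length(x))
}
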