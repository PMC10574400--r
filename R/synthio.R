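#' Build a circadian time-course sampling design
#'
#' The default reproduces the free-running (LL) design used throughout the
#' package: 12 timepoints at 4 h intervals starting at ZT24 (two continuous
#' days after one day of acclimation under constant light), with 2
#' (Arabidopsis-like) or 3 (soybean-like) biological replicates per
#' timepoint.
#'
#' @param n_timepoints number of timepoints (>= 4).
#' @param interval_h hours between consecutive timepoints (> 0).
#' @param start_zt zeitgeber time (hours) of the first timepoint.
#' @param replicates biological replicates per timepoint (>= 1).
#' @return an object of class `sampling_design`: a list with `timepoints`
#'   (ZT hours), `interval_h`, `replicates_per_timepoint`, and `samples`, a
#'   data.frame with one row per sample (`sample_id`, `zt_hour`,
#'   `replicate`).
#' @export
#' @examples
#' d <- make_design()            # 12 x 4 h from ZT24, 2 replicates
#' nrow(d$samples)               # 24 samples
make_design <- function(n_timepoints = 12, interval_h = 4, start_zt = 24,
                        replicates = 2) {
  .check(n_timepoints >= 4, "n_timepoints must be >= 4, got %s", n_timepoints)
  .check(interval_h > 0, "interval_h must be positive")
  .check(replicates >= 1, "replicates must be >= 1")
  tp <- start_zt + interval_h * (seq_len(n_timepoints) - 1)
  samples <- data.frame(
    sample_id = sprintf("ZT%g_r%d", rep(tp, each = replicates),
                        rep(seq_len(replicates), n_timepoints)),
    zt_hour = rep(tp, each = replicates),
    replicate = rep(seq_len(replicates), n_timepoints),
    stringsAsFactors = FALSE
  )
  structure(list(timepoints = tp, interval_h = interval_h,
                 replicates_per_timepoint = replicates, samples = samples),
            class = "sampling_design")
}

#' Default ground-truth parameter ranges for the simulator
#'
#' Rhythmic genes draw free-running periods near 24 h (U(20, 28) h), phases
#' uniform over the cycle, amplitudes of 0.5--3 log2 units and baselines of
#' 2--10 log2(CPM); all genes carry a small linear drift so that trend
#' handling in the fitter is exercised, and a negative-binomial dispersion in
#' the range typical of well-controlled bulk RNA-seq replicates.
#'
#' @return named list of `c(min, max)` ranges for `amplitude`, `period`,
#'   `phase24`, `constant`, `trend_slope` and `dispersion`.
#' @export
default_param_ranges <- function() {
  list(amplitude  = c(0.5, 3),
       period     = c(20, 28),
       phase24    = c(0, 24),
       constant   = c(2, 10),
       trend_slope = c(-0.02, 0.02),
       dispersion = c(0.01, 0.09))
}

# internal: draw a ground-truth parameter table
.simulate_truth <- function(n_genes, frac_rhythmic, ranges, prefix = "g") {
  .check(frac_rhythmic >= 0 && frac_rhythmic <= 1,
         "frac_rhythmic must be in [0, 1]")
  runif2 <- function(r, n) runif(n, r[1], r[2])
  n_r <- round(frac_rhythmic * n_genes)
  rhythmic <- rep(FALSE, n_genes)
  rhythmic[sample.int(n_genes, n_r)] <- TRUE
  truth <- data.frame(
    gene = sprintf("%s%04d", prefix, seq_len(n_genes)),
    rhythmic = rhythmic,
    amplitude = ifelse(rhythmic, runif2(ranges$amplitude, n_genes), 0),
    period = runif2(ranges$period, n_genes),
    phase24 = runif2(ranges$phase24, n_genes) %% 24,
    constant = runif2(ranges$constant, n_genes),
    trend_slope = runif2(ranges$trend_slope, n_genes),
    dispersion = runif2(ranges$dispersion, n_genes),
    stringsAsFactors = FALSE
  )
  truth
}

# internal: mean log2(CPM) surface implied by a truth table at times t
.truth_mean_log2cpm <- function(truth, t) {
  outer_arg <- outer(2 * pi / truth$period, t) -
    2 * pi / 24 * truth$phase24  # recycled by row
  truth$constant + outer(truth$trend_slope, t) +
    truth$amplitude * cos(outer_arg)
}

#' Simulate a circadian time-course count dataset with known ground truth
#'
#' Per gene, the mean log2 expression at ZT hour `t` is
#' `constant + trend_slope * t + amplitude * cos(2*pi/period * t -
#' 2*pi/24 * phase24)`; arrhythmic genes have amplitude 0. Counts are drawn
#' either as negative-binomial with mean `2^log2mean * libsize / 1e6` and
#' gene-level dispersion (the default, emulating a raw RNA-seq count
#' matrix), or as rounded lognormal noise on the log2 scale with standard
#' deviation `sd_log2`. Library sizes are drawn log-uniformly within a
#' factor of 2 of `lib_size_nominal` so that library-size normalization is
#' non-trivial.
#'
#' @param design a [make_design()] object.
#' @param n_genes number of genes.
#' @param frac_rhythmic fraction of genes that are rhythmic (amplitude > 0).
#' @param param_ranges sampling ranges, see [default_param_ranges()].
#' @param noise_model `"nb"` (negative binomial counts) or `"lognormal"`.
#' @param sd_log2 log2-scale noise sd for the lognormal model.
#' @param lib_size_nominal nominal library size (reads per sample).
#' @param seed integer seed; the dataset is fully reproducible given it.
#' @param truth optional pre-built truth table (e.g. from
#'   [make_homolog_truth()]); overrides `n_genes`/`frac_rhythmic`.
#' @param gene_prefix prefix for generated gene ids.
#' @return an object of class `synthetic_dataset`: list with `counts`
#'   (gene x sample integer matrix), `design`, `truth`, `library_sizes`
#'   (drawn target sizes) and `homolog_map` (NULL unless attached).
#' @export
#' @examples
#' ds <- simulate_dataset(make_design(), n_genes = 50, seed = 1)
#' dim(ds$counts)
simulate_dataset <- function(design, n_genes = 2000, frac_rhythmic = 0.45,
                             param_ranges = default_param_ranges(),
                             noise_model = c("nb", "lognormal"),
                             sd_log2 = 0.25, lib_size_nominal = 2e7,
                             seed = 1, truth = NULL, gene_prefix = "g") {
  .check(inherits(design, "sampling_design"), "design must be a sampling_design")
  .check(nrow(design$samples) > 0, "empty design")
  noise_model <- match.arg(noise_model)
  set.seed(seed)
  if (is.null(truth)) {
    truth <- .simulate_truth(n_genes, frac_rhythmic, param_ranges, gene_prefix)
  }
  n_genes <- nrow(truth)
  t <- design$samples$zt_hour
  n_samp <- length(t)
  lib <- round(exp(runif(n_samp, log(lib_size_nominal / 2),
                         log(lib_size_nominal * 2))))
  m <- .truth_mean_log2cpm(truth, t)  # genes x samples, log2(CPM) scale
  mu <- 2^m * rep(lib / 1e6, each = n_genes)
  counts <- switch(noise_model,
    nb = matrix(rnbinom(length(mu), mu = mu,
                        size = rep(1 / pmax(truth$dispersion, 1e-8), n_samp)),
                nrow = n_genes),
    lognormal = round(2^(m + matrix(rnorm(length(mu), sd = sd_log2),
                                    nrow = n_genes)) *
                      rep(lib / 1e6, each = n_genes))
  )
  dimnames(counts) <- list(truth$gene, design$samples$sample_id)
  structure(list(counts = counts, design = design, truth = truth,
                 library_sizes = stats::setNames(lib, design$samples$sample_id),
                 homolog_map = NULL),
            class = "synthetic_dataset")
}

#' Generate paired ground truth for homologous genes with designed shifts
#'
#' Species-B truth equals species-A truth with a phase shift (wrapped onto
#' `[0, 24)`), a period shift, and an amplitude ratio applied, mirroring the
#' designed cross-species contrasts used to validate the homolog analysis
#' (e.g. a clock-gene phase shifting from 15.87 h to 14.11 h is a -1.76 h
#' phase shift).
#'
#' @param n_pairs number of homolog pairs.
#' @param shift_spec list with `phase_shift_h`, `period_shift_h`,
#'   `amplitude_ratio` (scalars or length-`n_pairs` vectors).
#' @param param_ranges sampling ranges for the species-A draw; all pairs are
#'   rhythmic.
#' @param seed integer seed.
#' @param prefix_a,prefix_b gene-id prefixes for the two species.
#' @return list with `map` (data.frame `gene_a`, `gene_b`), `truth_a`,
#'   `truth_b`, and `shift_spec`.
#' @export
#' @examples
#' h <- make_homolog_truth(5, list(phase_shift_h = -1.76,
#'                                 period_shift_h = 0, amplitude_ratio = 0.5),
#'                         seed = 1)
#' h$map
make_homolog_truth <- function(n_pairs,
                               shift_spec = list(phase_shift_h = 0,
                                                 period_shift_h = 0,
                                                 amplitude_ratio = 1),
                               param_ranges = default_param_ranges(),
                               seed = 1, prefix_a = "ath", prefix_b = "gmx") {
  .check(n_pairs >= 1, "n_pairs must be >= 1")
  .check(all(c("phase_shift_h", "period_shift_h", "amplitude_ratio") %in%
             names(shift_spec)), "shift_spec is missing fields")
  set.seed(seed)
  truth_a <- .simulate_truth(n_pairs, 1, param_ranges, prefix_a)
  truth_b <- truth_a
  truth_b$gene <- sub(prefix_a, prefix_b, truth_a$gene, fixed = TRUE)
  truth_b$phase24 <- wrap24(truth_a$phase24 + shift_spec$phase_shift_h)
  truth_b$period <- truth_a$period + shift_spec$period_shift_h
  .check(all(truth_b$period > 12 & truth_b$period < 36),
         "period shift pushes a pair outside (12, 36) h")
  .check(all(shift_spec$amplitude_ratio >= 0), "amplitude_ratio must be >= 0")
  truth_b$amplitude <- truth_a$amplitude * shift_spec$amplitude_ratio
  truth_b$rhythmic <- truth_b$amplitude > 0
  list(map = data.frame(gene_a = truth_a$gene, gene_b = truth_b$gene,
                        stringsAsFactors = FALSE),
       truth_a = truth_a, truth_b = truth_b, shift_spec = shift_spec)
}

#' Simulate a two-species dataset pair with designed homolog shifts
#'
#' Convenience wrapper for end-to-end runs: draws independent background
#' truths for each species, appends `n_pairs` homolog pairs with the
#' designed parameter shifts, and simulates counts for both species on
#' their own sampling designs.
#'
#' @param design_a,design_b sampling designs for the two species.
#' @param n_genes genes per species (including the homolog pairs).
#' @param frac_rhythmic fraction rhythmic among background genes.
#' @param n_pairs number of designed homolog pairs.
#' @param shift_spec see [make_homolog_truth()].
#' @param seed integer seed.
#' @param ... further arguments to [simulate_dataset()].
#' @return list with `a`, `b` (synthetic_dataset objects, homolog map
#'   attached to both) and `homologs` (the [make_homolog_truth()] output).
#' @export
simulate_species_pair <- function(design_a = make_design(replicates = 2),
                                  design_b = make_design(replicates = 3),
                                  n_genes = 2000, frac_rhythmic = 0.45,
                                  n_pairs = 20,
                                  shift_spec = list(phase_shift_h = -1.76,
                                                    period_shift_h = 0,
                                                    amplitude_ratio = 0.5),
                                  seed = 1, ...) {
  .check(n_pairs < n_genes, "n_pairs must be smaller than n_genes")
  hom <- make_homolog_truth(n_pairs, shift_spec, seed = seed)
  set.seed(seed + 1)
  bg_a <- .simulate_truth(n_genes - n_pairs, frac_rhythmic,
                          default_param_ranges(), "at")
  set.seed(seed + 2)
  bg_b <- .simulate_truth(n_genes - n_pairs, frac_rhythmic,
                          default_param_ranges(), "gm")
  truth_a <- rbind(bg_a, hom$truth_a)
  truth_b <- rbind(bg_b, hom$truth_b)
  ds_a <- simulate_dataset(design_a, truth = truth_a, seed = seed + 3, ...)
  ds_b <- simulate_dataset(design_b, truth = truth_b, seed = seed + 4, ...)
  ds_a$homolog_map <- hom$map
  ds_b$homolog_map <- hom$map
  list(a = ds_a, b = ds_b, homologs = hom)
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Writes `counts.tsv` (first column `gene`, then sample columns),
#' `samples.tsv` (`sample_id`, `zt_hour`, `replicate`), `truth.tsv`,
#' and, when present, `homologs.tsv` (`gene_a`, `gene_b`). Files round-trip
#' through [read_counts()] without loss.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_fixture <- function(dataset, dir) {
  .check(inherits(dataset, "synthetic_dataset"),
         "dataset must be a synthetic_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  counts_df <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$design$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dataset$homolog_map)) {
    paths <- c(paths, homologs = file.path(dir, "homologs.tsv"))
    utils::write.table(dataset$homolog_map, paths["homologs"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a counts TSV and sample sheet into a time-course object
#'
#' @param counts_path TSV with first column `gene` and one column per sample.
#' @param samples_path TSV with columns `sample_id`, `zt_hour`, `replicate`.
#' @return a `timecourse` object, see [timecourse()].
#' @export
read_counts <- function(counts_path, samples_path) {
  cdf <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  timecourse(counts, samples)
}

#' Generate random gene sets and/or write them in GMT format
#'
#' @param gene_ids universe of gene ids to draw from.
#' @param n_sets number of sets.
#' @param size_range `c(min, max)` set sizes.
#' @param seed integer seed.
#' @return named list of character vectors, with a `description` attribute
#'   per set stored in `attr(x, "descriptions")`.
#' @export
make_gene_sets <- function(gene_ids, n_sets = 50, size_range = c(5, 100),
                           seed = 1) {
  .check(length(gene_ids) >= size_range[2],
         "universe smaller than maximum set size")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  attr(sets, "descriptions") <-
    stats::setNames(sprintf("synthetic random set of %d genes", sizes),
                    names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector (recycled if length 1);
#'   defaults to the `descriptions` attribute or `"NA"`.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions)) descriptions <- rep("NA", length(sets))
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .check(all(lengths(parts) >= 3), "malformed GMT line (need id, desc, gene+)")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}
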