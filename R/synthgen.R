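#' Default diagnosis-stage proportions
#'
#' Pooled stage composition of a two-site depression cohort staged by
#' HAM-D24: 64 healthy controls, 78 moderate and 29 severe patients out of
#' 171 subjects.
#' @return named numeric vector summing to 1.
#' @export
default_stage_proportions <- function() {
  c(HC = 64, MD = 78, SD = 29) / 171
}

#' Simulate diagnosis-stage labels
#'
#' Deterministic stage counts (proportions rounded to the cohort size,
#' remainder given to the largest groups) in a seeded random order, so
#' stratified folds behave like the real three-stage cohort.
#'
#' @param n number of subjects.
#' @param proportions named proportions over stages, summing to 1.
#' @param seed RNG seed.
#' @return character vector of length n.
#' @export
simulate_stages <- function(n, proportions = default_stage_proportions(),
                            seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, n >= length(proportions))
  counts <- floor(proportions * n)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(-(proportions * n - counts))[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(proportions), counts)
  with_seed(seed, labels[sample.int(n)])
}

#' Simulate an additively coded SNP under Hardy-Weinberg equilibrium
#'
#' Minor-allele counts per subject are Binomial(2, maf), giving genotype
#' codes 0/1/2 with HWE frequencies `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param n number of subjects.
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @param seed RNG seed.
#' @return integer vector in `{0, 1, 2}`.
#' @export
simulate_genotype <- function(n, maf = 0.3, seed = 1L) {
  if (!(maf > 0 && maf <= 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  with_seed(seed, stats::rbinom(n, 2L, maf))
}

#' Simulate a two-modality feature dataset with planted sparse support
#'
#' Generates M = 2 modality matrices (N x d) in which a common set of
#' `support_size` feature rows carries a linear genotype signal with
#' modality-specific coefficients `c^m_j ~ N(1, 0.1)`, every subject of a
#' stage shares a stage-specific mean shift, and everything else is
#' Gaussian noise:
#' \deqn{X^m_{ij} = \beta\, g_i\, c^m_j\, 1[j \in R] +
#'       \delta\, \mu_{stage(i), j} + \varepsilon_{ij},\quad
#'       \varepsilon \sim N(0, \sigma^2).}
#' The generator inverts the model's reading of the data: the genotype is
#' the cause and the imaging features the effect, while the model regresses
#' genotype on features (phenotype-to-genotype direction). Stage structure
#' enters as within-stage common shifts, exactly the structure the
#' stage-Laplacian penalty exploits.
#'
#' @param genotype length-N additive genotype vector (see
#'   [simulate_genotype()]).
#' @param stages length-N stage labels (see [simulate_stages()]).
#' @param d number of features per modality (default 116, the AAL atlas).
#' @param support_size number of causal feature rows (default 10).
#' @param effect_size genotype effect beta (default 0.5).
#' @param stage_shift stage-shift scale delta (default 0.5).
#' @param noise_sd noise standard deviation sigma (default 1).
#' @param seed RNG seed.
#' @return list with `X` (named list of `node` and `edge` matrices with ROI
#'   column names), `y` (= genotype), `stages`, `support` (causal feature
#'   indices), `coefficients` (per-modality causal coefficients),
#'   `stage_means`, and the configuration.
#' @export
simulate_features <- function(genotype, stages, d = 116L, support_size = 10L,
                              effect_size = 0.5, stage_shift = 0.5,
                              noise_sd = 1, seed = 1L) {
  n <- length(genotype)
  if (length(stages) != n)
    stop("genotype and stages must have equal length", call. = FALSE)
  stopifnot(support_size <= d, support_size >= 1)
  roi <- roi_names_for(d)
  stage_levels <- sort(unique(as.character(stages)))
  mods <- c("node", "edge")
  with_seed(seed, {
    support <- sort(sample.int(d, support_size))
    coefs <- lapply(mods, function(m)
      stats::rnorm(support_size, mean = 1, sd = 0.1))
    names(coefs) <- mods
    stage_means <- matrix(stats::rnorm(length(stage_levels) * d),
                          length(stage_levels), d,
                          dimnames = list(stage_levels, roi))
    X <- lapply(mods, function(m) {
      cm <- numeric(d)
      cm[support] <- coefs[[m]]
      signal <- effect_size * outer(as.numeric(genotype), cm)
      shift <- stage_shift * stage_means[as.character(stages), , drop = FALSE]
      noise <- matrix(stats::rnorm(n * d, sd = noise_sd), n, d)
      out <- signal + shift + noise
      dimnames(out) <- list(NULL, roi)
      out
    })
    names(X) <- mods
    list(X = X, y = as.numeric(genotype), stages = as.character(stages),
         support = support, coefficients = coefs, stage_means = stage_means,
         config = list(d = d, support_size = support_size,
                       effect_size = effect_size, stage_shift = stage_shift,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: stages, HWE genotype, then the two-modality feature
#' matrices, all derived from one base seed.
#'
#' The modeled SNP is a disease-risk variant, so its minor-allele frequency
#' rises with diagnosis severity by default: genotypes are drawn under HWE
#' *within* each stage at that stage's frequency. This genotype-stage
#' association is what lets the diagnosis-stage Laplacian carry information
#' about the genotype; pass a single number to `maf` for a variant
#' unrelated to disease stage.
#'
#' @param n number of subjects (default 150).
#' @param maf minor-allele frequency: a single value in (0, 0.5], or a
#'   named per-stage vector (default `c(HC = 0.2, MD = 0.35, SD = 0.45)`,
#'   pooled frequency about 0.3 at the default stage proportions).
#' @param proportions stage proportions (default
#'   [default_stage_proportions()]).
#' @param seed base seed; sub-generators use fixed offsets from it.
#' @inheritParams simulate_features
#' @return as [simulate_features()], plus `subject_id`.
#' @export
simulate_cohort <- function(n = 150L, d = 116L,
                            maf = c(HC = 0.2, MD = 0.35, SD = 0.45),
                            proportions = default_stage_proportions(),
                            support_size = 10L, effect_size = 0.5,
                            stage_shift = 0.5, noise_sd = 1, seed = 1L) {
  stages <- simulate_stages(n, proportions, seed = seed + 11L)
  if (length(maf) == 1L) {
    g <- simulate_genotype(n, maf, seed = seed + 23L)
  } else {
    if (!all(unique(stages) %in% names(maf)))
      stop("per-stage maf must name every stage", call. = FALSE)
    g <- integer(n)
    for (s in unique(stages)) {
      idx <- which(stages == s)
      g[idx] <- simulate_genotype(length(idx), maf[[s]],
                                  seed = seed + 23L + match(s, names(maf)))
    }
  }
  out <- simulate_features(g, stages, d = d, support_size = support_size,
                           effect_size = effect_size,
                           stage_shift = stage_shift, noise_sd = noise_sd,
                           seed = seed + 37L)
  out$subject_id <- sprintf("sub%04d", seq_len(n))
  for (m in seq_along(out$X)) rownames(out$X[[m]]) <- out$subject_id
  out
}

#' Simulate block-structured ROI BOLD time series
#'
#' Each subject's d ROIs are split into contiguous communities; within a
#' community every pair of series shares a latent factor so the expected
#' pairwise correlation equals `rho` for the subject's stage. Series are
#' unit-variance Gaussian.
#'
#' @param stages stage labels, one per subject.
#' @param d number of ROIs.
#' @param timepoints series length T (>= 3).
#' @param n_blocks number of communities.
#' @param rho named vector of within-block target correlations per stage
#'   (entries in `[0, 1)`); unnamed scalar = same for all stages.
#' @param seed RNG seed.
#' @return named list (by subject id) of T x d matrices with ROI column
#'   names; attribute `blocks` gives the community assignment.
#' @export
simulate_timeseries <- function(stages, d = 10L, timepoints = 100L,
                                n_blocks = 2L,
                                rho = c(HC = 0.2, MD = 0.4, SD = 0.6),
                                seed = 1L) {
  stopifnot(d >= 2L, timepoints >= 3L, n_blocks >= 1L)
  stages <- as.character(stages)
  if (is.null(names(rho))) rho <- stats::setNames(rep(rho[1], length(unique(stages))),
                                                  unique(stages))
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  roi <- roi_names_for(d)
  blocks <- rep(seq_len(n_blocks), length.out = d)
  out <- with_seed(seed, lapply(seq_along(stages), function(i) {
    r <- rho[[stages[i]]]
    f <- matrix(stats::rnorm(timepoints * n_blocks), timepoints, n_blocks)
    eps <- matrix(stats::rnorm(timepoints * d), timepoints, d)
    ts <- sqrt(r) * f[, blocks, drop = FALSE] + sqrt(1 - r) * eps
    dimnames(ts) <- list(NULL, roi)
    ts
  }))
  names(out) <- sprintf("sub%04d", seq_along(stages))
  attr(out, "blocks") <- blocks
  out
}

#' Simulate a density volume plus matching atlas
#'
#' Builds a 3-D array of `d_regions` contiguous labeled blocks; each
#' region's density is a region mean plus voxel noise. The true means are
#' returned so extraction can be checked against ground truth.
#'
#' @param d_regions number of atlas regions.
#' @param voxels_per_region voxels in each region.
#' @param noise_sd voxel noise standard deviation.
#' @param seed RNG seed.
#' @return list with `density` (3-D array), `atlas` (3-D integer array,
#'   0 = background), `label_map` (data frame: label, roi), and
#'   `true_means`.
#' @export
simulate_atlas_volume <- function(d_regions, voxels_per_region = 27L,
                                  noise_sd = 0.05, seed = 1L) {
  stopifnot(d_regions >= 1L, voxels_per_region >= 1L)
  n_vox <- d_regions * voxels_per_region
  nx <- max(2L, ceiling(n_vox^(1 / 3)))
  dims <- c(nx, nx, ceiling(n_vox / nx^2) + 1L)
  total <- prod(dims)
  atlas <- integer(total)
  atlas[seq_len(n_vox)] <- rep(seq_len(d_regions), each = voxels_per_region)
  with_seed(seed, {
    means <- stats::runif(d_regions, 0.2, 0.9)
    density <- numeric(total)
    density[atlas > 0] <- means[atlas[atlas > 0]] +
      stats::rnorm(n_vox, sd = noise_sd)
    dim(atlas) <- dims
    dim(density) <- dims
    list(density = density, atlas = atlas,
         label_map = data.frame(label = seq_len(d_regions),
                                roi = roi_names_for(d_regions),
                                stringsAsFactors = FALSE),
         true_means = stats::setNames(means, roi_names_for(d_regions)))
  })
}

#' ROI name set of a given size
#'
#' Returns the packaged 116-region AAL label list when `d == 116`, otherwise
#' generic zero-padded ROI labels.
#' @param d number of regions.
#' @return character vector of length d.
#' @export
roi_names_for <- function(d) {
  if (d == 116L) return(aal116_names())
  sprintf("ROI_%03d", seq_len(d))
}

#' The 116 AAL atlas region names
#'
#' @return character vector of 116 region labels shipped with the package.
#' @export
aal116_names <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "msdmm")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$roi
}
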