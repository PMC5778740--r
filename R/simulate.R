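#' ID-Migraine screening classification
#'
#' The three-item screener records photophobia, nausea and headache-related
#' disability; respondents affirming two or three items are classified as
#' migraine cases.
#'
#' @param items logical vector of length 3, or an n x 3 logical matrix
#'   (columns photophobia, nausea, disability).
#' @return character vector: "case" or "non_case".
#' @export
classify_id_migraine <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    if (ncol(items) != 3) stop("`items` must have exactly 3 columns")
    if (anyNA(items)) stop("`items` must not contain NA")
    k <- rowSums(items)
  } else {
    if (length(items) != 3) stop("`items` must have exactly 3 entries")
    if (anyNA(items)) stop("`items` must not contain NA")
    k <- sum(items)
  }
  ifelse(k >= 2, "case", "non_case")
}

#' Study design emulated by the sample simulator
#'
#' Group sizes, female counts and age distributions (mean/SD in years) of the
#' matched case/control design the generator reproduces by default: 28 adult
#' and 39 adolescent cases, each age- and sex-matched to an unrelated control,
#' 134 individuals in total.
#'
#' @return data.frame with one row per cohort x status cell.
#' @export
default_study_design <- function() {
  data.frame(
    cohort = rep(c("adult", "adolescent"), each = 2),
    status = rep(c("case", "control"), 2),
    n = c(28L, 28L, 39L, 39L),
    n_female = c(15L, 15L, 16L, 16L),
    age_mean = c(48.00, 46.25, 14.20, 14.03),
    age_sd = c(7.90, 5.23, 2.36, 2.08),
    age_min = c(33, 33, 12, 12),
    age_max = c(74, 74, 19, 19),
    stringsAsFactors = FALSE
  )
}

#' Cell-type mixture configuration for the simulator
#'
#' Describes the latent leukocyte-like composition structure folded into
#' simulated beta values: `n_cell_types` components with per-sample mixing
#' proportions drawn from a Dirichlet distribution. A small fraction of
#' probes is strongly cell-type informative (large per-cell-type offsets, the
#' signal sparse-PCA correction keys on), while all remaining probes carry a
#' weak loading so that composition shifts move the genome-wide test-statistic
#' median, as they do in whole blood. `case_control_shift` is added to the
#' mean mixing proportions of cases (then renormalised), injecting
#' composition confounding.
#'
#' @param n_cell_types number of latent cell types.
#' @param dirichlet_concentration positive concentration parameters, length
#'   `n_cell_types`.
#' @param informative_fraction fraction of probes with strong cell-type
#'   offsets.
#' @param informative_sd SD of per-cell-type beta offsets at informative
#'   probes.
#' @param background_sd SD of offsets at all other probes.
#' @param case_control_shift numeric length `n_cell_types`; additive shift of
#'   case mean proportions (zero = no confounding).
#' @param profiles optional pre-built probe x cell-type offset matrix; `NULL`
#'   draws offsets from the SDs above.
#' @return list of class `cell_type_config`.
#' @export
cell_type_config <- function(n_cell_types = 5,
                             dirichlet_concentration = c(12, 6, 3, 2, 1),
                             informative_fraction = 0.05,
                             informative_sd = 0.15,
                             background_sd = 0.03,
                             case_control_shift = rep(0, n_cell_types),
                             profiles = NULL) {
  if (length(dirichlet_concentration) != n_cell_types)
    stop("`dirichlet_concentration` must have length n_cell_types")
  if (any(dirichlet_concentration <= 0))
    stop("`dirichlet_concentration` must be positive")
  if (length(case_control_shift) != n_cell_types)
    stop("`case_control_shift` must have length n_cell_types")
  structure(list(
    n_cell_types = n_cell_types,
    dirichlet_concentration = dirichlet_concentration,
    informative_fraction = informative_fraction,
    informative_sd = informative_sd,
    background_sd = background_sd,
    case_control_shift = case_control_shift,
    profiles = profiles
  ), class = "cell_type_config")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Pick spike-in regions from a manifest
#'
#' Selects non-overlapping runs of `n_probes` consecutive probes whose
#' genomic span falls in \[`min_span`, `max_span`\] bp, suitable as ground-truth
#' differentially methylated regions. Signs of `delta_beta` alternate when a
#' single magnitude is supplied.
#'
#' @param manifest probe manifest sorted by (chrom, pos).
#' @param n_regions number of regions to place.
#' @param delta_beta effect size(s); a scalar is expanded to alternating
#'   +/- signs.
#' @param n_probes probes per region.
#' @param min_span,max_span admissible region widths in bp.
#' @param max_gap largest tolerated distance between consecutive probes in a
#'   region (default 900 bp, keeping regions CpG-dense the way real DMRs
#'   are; a sliding-window caller cannot bridge gaps wider than its window).
#' @param min_separation minimum bp between chosen regions.
#' @param seed optional integer seed.
#' @return data.frame `chrom`, `start`, `end`, `delta_beta`, `n_probes`
#'   (1-based inclusive coordinates).
#' @export
sample_spike_regions <- function(manifest, n_regions, delta_beta = 0.10,
                                 n_probes = 12, min_span = 2500,
                                 max_span = 6000, max_gap = 900,
                                 min_separation = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(delta_beta) == 1)
    delta_beta <- delta_beta * rep(c(1, -1), length.out = n_regions)
  if (length(delta_beta) != n_regions)
    stop("`delta_beta` must be scalar or length n_regions")
  n <- nrow(manifest)
  if (n < n_probes) stop("manifest too small for requested spikes")
  i <- seq_len(n - n_probes + 1)
  j <- i + n_probes - 1
  same_chrom <- manifest$chrom[i] == manifest$chrom[j]
  span <- manifest$pos[j] - manifest$pos[i]
  gap <- c(diff(manifest$pos), Inf)
  gap[which(manifest$chrom[-1] != manifest$chrom[-n])] <- Inf
  # largest consecutive gap inside each candidate run of n_probes probes
  run_max_gap <- vapply(i, function(s) max(gap[s:(s + n_probes - 2)]), numeric(1))
  ok <- which(same_chrom & span >= min_span & span <= max_span &
                run_max_gap <= max_gap)
  if (!length(ok)) stop("no candidate runs satisfy the span constraints")
  chosen <- integer(0)
  for (cand in sample(ok)) {
    if (length(chosen) == n_regions) break
    clash <- any(manifest$chrom[chosen] == manifest$chrom[cand] &
                   abs(manifest$pos[chosen] - manifest$pos[cand]) <
                     (max_span + min_separation))
    if (!clash) chosen <- c(chosen, cand)
  }
  if (length(chosen) < n_regions)
    stop("could only place ", length(chosen), " of ", n_regions,
         " spike regions; relax the constraints or enlarge the manifest")
  chosen <- sort(chosen)
  data.frame(
    chrom = manifest$chrom[chosen],
    start = manifest$pos[chosen],
    end = manifest$pos[chosen + n_probes - 1],
    delta_beta = delta_beta[seq_len(n_regions)],
    n_probes = n_probes,
    stringsAsFactors = FALSE
  )
}

#' Simulate a matched case/control sample sheet
#'
#' Draws cases per cohort from the default study design (ages truncated
#' normal per cohort) and pairs each with a control of the same cohort and
#' sex, aged within +/- 2 years. Extra controls beyond `n_cases` are drawn
#' unmatched. Chips hold 12 samples; samples are shuffled onto chips so chip
#' is not confounded with status. ID-Migraine item triples are generated
#' consistently with status (cases affirm >= 2 items, controls < 2).
#'
#' @param n_cases,n_controls group sizes.
#' @param cohort_split named proportions (`adult`, `adolescent`) of cases;
#'   default follows the design table.
#' @param seed optional integer seed.
#' @return data.frame sample sheet.
#' @export
simulate_samples <- function(n_cases = 67, n_controls = 67,
                             cohort_split = c(adult = 28 / 67, adolescent = 39 / 67),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  des <- default_study_design()
  n_adult <- round(n_cases * cohort_split[["adult"]])
  coh <- c(rep("adult", n_adult), rep("adolescent", n_cases - n_adult))
  draw_age <- function(cohort, status, n) {
    d <- des[des$cohort == cohort & des$status == status, ]
    pmin(pmax(stats::rnorm(n, d$age_mean, d$age_sd), d$age_min), d$age_max)
  }
  p_female <- function(cohort) {
    d <- des[des$cohort == cohort & des$status == "case", ]
    d$n_female / d$n
  }
  sex <- ifelse(stats::runif(n_cases) < vapply(coh, p_female, numeric(1)), "F", "M")
  age <- numeric(n_cases)
  for (cohort in unique(coh)) {
    idx <- coh == cohort
    age[idx] <- draw_age(cohort, "case", sum(idx))
  }
  cases <- data.frame(status = "case", cohort = coh, sex = sex, age = age,
                      stringsAsFactors = FALSE)
  n_matched <- min(n_cases, n_controls)
  ctrl <- cases[seq_len(n_matched), , drop = FALSE]
  ctrl$status <- "control"
  ctrl$age <- pmin(pmax(ctrl$age + stats::runif(n_matched, -2, 2), 12), 74)
  if (n_controls > n_matched) {
    k <- n_controls - n_matched
    coh2 <- sample(c("adult", "adolescent"), k, TRUE, prob = cohort_split)
    extra <- data.frame(status = "control", cohort = coh2,
                        sex = sample(c("F", "M"), k, TRUE),
                        age = vapply(coh2, function(ch) draw_age(ch, "control", 1), numeric(1)),
                        stringsAsFactors = FALSE)
    ctrl <- rbind(ctrl, extra)
  }
  sheet <- rbind(cases, ctrl)
  n <- nrow(sheet)
  if (n == 0) {
    return(data.frame(sample_id = character(0), status = character(0),
                      cohort = character(0), age = numeric(0), sex = character(0),
                      chip = character(0), chip_position = character(0),
                      photophobia = logical(0), nausea = logical(0),
                      disability = logical(0)))
  }
  sheet$sample_id <- sprintf("S%04d", seq_len(n))
  ord <- sample.int(n)          # randomise chip assignment
  chip_slot <- integer(n)
  chip_slot[ord] <- seq_len(n)
  sheet$chip <- sprintf("chip%02d", (chip_slot - 1L) %/% 12L + 1L)
  within <- (chip_slot - 1L) %% 12L
  sheet$chip_position <- sprintf("R%02dC%02d", within %% 6L + 1L, within %/% 6L + 1L)
  n_items <- ifelse(sheet$status == "case",
                    ifelse(stats::runif(n) < 0.5, 2L, 3L),
                    ifelse(stats::runif(n) < 0.7, 0L, 1L))
  items <- t(vapply(n_items, function(k) {
    v <- logical(3)
    v[sample.int(3, k)] <- TRUE
    v
  }, logical(3)))
  sheet$photophobia <- items[, 1]
  sheet$nausea <- items[, 2]
  sheet$disability <- items[, 3]
  rownames(sheet) <- NULL
  sheet[, c("sample_id", "status", "cohort", "age", "sex", "chip",
            "chip_position", "photophobia", "nausea", "disability")]
}

#' Simulate a methylation dataset with known ground truth
#'
#' Baseline per-probe means are drawn from a three-mode mixture (Beta-like
#' modes near 0.1, 0.5 and 0.9) so that, as on real arrays, beta values mass
#' at the extremes with an intermediate component. Cell-type structure is
#' added as probe-specific offsets weighted by per-sample Dirichlet mixing
#' proportions; since proportions sum to one, adding a regional case shift to
#' every cell-type profile is identical to adding it after mixing, which is
#' how it is applied. Technical covariate effects (age, sex, chip) act on the
#' logit scale at a random subset of probes. Spiked regions shift case
#' samples by `delta_beta` at every probe inside the region; the returned
#' `truth` table is the spike list verbatim.
#'
#' @param manifest probe manifest from [generate_manifest()].
#' @param n_cases,n_controls group sizes (default 67 + 67).
#' @param cohort_split case proportions per cohort.
#' @param spikes `NULL` or a data.frame `chrom`, `start`, `end`, `delta_beta`
#'   (1-based inclusive), e.g. from [sample_spike_regions()].
#' @param celltype a [cell_type_config()].
#' @param noise_sd measurement-noise scale: the beta-scale SD at beta = 0.5
#'   (noise is Gaussian on the latent logit, so its beta-scale spread
#'   shrinks toward 0 and 1 as on real arrays).
#' @param mixture_weights weights of the low/intermediate/high baseline modes.
#' @param covariate_fraction fraction of probes with technical covariate
#'   effects; `covariate_sd` is the SD of their logit-scale coefficients.
#' @param detection_fail_rate fraction of entries with failed detection
#'   (detection P well above 0.001).
#' @param missing_rate fraction of beta entries set missing.
#' @param covariate_sd logit-scale SD of technical effects.
#' @param seed optional integer seed driving every draw.
#' @return list with `dataset` (a [meth_set()]), `truth` (ground-truth DMR
#'   table) and `celltype_proportions` (samples x cell types).
#' @export
simulate_dataset <- function(manifest, n_cases = 67, n_controls = 67,
                             cohort_split = c(adult = 28 / 67, adolescent = 39 / 67),
                             spikes = NULL, celltype = cell_type_config(),
                             noise_sd = 0.04,
                             mixture_weights = c(0.35, 0.25, 0.40),
                             covariate_fraction = 0.10, covariate_sd = 0.10,
                             detection_fail_rate = 0.002, missing_rate = 0.001,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cases < 0 || n_controls < 0) stop("sample counts must be non-negative")
  n_probes <- nrow(manifest)
  sheet <- simulate_samples(n_cases, n_controls, cohort_split)
  n <- nrow(sheet)
  is_case <- sheet$status == "case"

  # spike validation against the manifest span
  spike_idx <- list()
  if (!is.null(spikes) && nrow(spikes)) {
    for (r in seq_len(nrow(spikes))) {
      s <- spikes[r, ]
      on_chrom <- manifest$chrom == s$chrom
      if (!any(on_chrom))
        stop("spike region ", r, " on ", s$chrom, " is outside the manifest span")
      idx <- which(on_chrom & manifest$pos >= s$start & manifest$pos <= s$end)
      if (!length(idx))
        stop("spike region ", r, " covers no probes")
      if (abs(s$delta_beta) > 0.25)
        stop("spike |delta_beta| must be <= 0.25")
      if (s$end <= s$start) stop("spike end must exceed start")
      spike_idx[[r]] <- idx
    }
  }

  # baseline means: 3-mode mixture near 0.1 / 0.5 / 0.9
  comp <- sample.int(3, n_probes, TRUE, prob = mixture_weights)
  mu <- numeric(n_probes)
  mu[comp == 1] <- stats::rbeta(sum(comp == 1), 5, 45)
  mu[comp == 2] <- stats::rbeta(sum(comp == 2), 20, 20)
  mu[comp == 3] <- stats::rbeta(sum(comp == 3), 45, 5)

  # cell-type offsets and mixing proportions
  K <- celltype$n_cell_types
  if (is.null(celltype$profiles)) {
    off <- matrix(stats::rnorm(n_probes * K, 0, celltype$background_sd),
                  n_probes, K)
    inf_idx <- stats::runif(n_probes) < celltype$informative_fraction
    off[inf_idx, ] <- stats::rnorm(sum(inf_idx) * K, 0, celltype$informative_sd)
  } else {
    off <- celltype$profiles
    if (!identical(dim(off), c(n_probes, K)))
      stop("celltype$profiles must be n_probes x n_cell_types")
  }
  alpha <- celltype$dirichlet_concentration
  base_mean <- alpha / sum(alpha)
  case_mean <- base_mean + celltype$case_control_shift
  if (any(case_mean <= 0)) stop("case_control_shift drives a proportion below zero")
  case_mean <- case_mean / sum(case_mean)
  W <- matrix(0, n, K)
  if (any(!is_case)) W[!is_case, ] <- .rdirichlet(sum(!is_case), alpha)
  if (any(is_case)) W[is_case, ] <- .rdirichlet(sum(is_case), case_mean * sum(alpha))
  # centre the offsets' contribution so mu stays the probe mean
  beta <- matrix(mu, n_probes, n) + off %*% t(W - matrix(base_mean, n, K, byrow = TRUE))

  # spikes: cases only, constant shift across the region
  for (r in seq_along(spike_idx)) {
    beta[spike_idx[[r]], is_case] <- beta[spike_idx[[r]], is_case] + spikes$delta_beta[r]
  }

  # move to the latent logit scale for technical effects and measurement
  # noise: array noise is largest at intermediate beta and shrinks toward the
  # boundaries, so Gaussian noise on the logit (scaled to have SD `noise_sd`
  # on the beta scale at beta = 0.5) reproduces that shape and never emits
  # an exact 0 or 1
  lat <- stats::qlogis(pmin(pmax(beta, 0.005), 0.995))
  if (covariate_fraction > 0 && n > 0) {
    tech <- which(stats::runif(n_probes) < covariate_fraction)
    if (length(tech)) {
      age_z <- as.numeric(scale(sheet$age))
      sex_f <- as.numeric(sheet$sex == "F")
      chip_lev <- unique(sheet$chip)
      chip_eff <- matrix(stats::rnorm(length(tech) * length(chip_lev), 0, covariate_sd),
                         length(tech), length(chip_lev))
      b_age <- stats::rnorm(length(tech), 0, covariate_sd)
      b_sex <- stats::rnorm(length(tech), 0, covariate_sd)
      lat[tech, ] <- lat[tech, , drop = FALSE] + outer(b_age, age_z) +
        outer(b_sex, sex_f) +
        chip_eff[, match(sheet$chip, chip_lev), drop = FALSE]
    }
  }
  noise_logit <- noise_sd / 0.25  # d beta / d logit = 0.25 at beta 0.5
  lat <- lat + matrix(stats::rnorm(n_probes * n, 0, noise_logit), n_probes, n)
  beta <- stats::plogis(lat)

  detection_p <- matrix(stats::runif(n_probes * n, 0, 1e-4), n_probes, n)
  if (detection_fail_rate > 0 && length(detection_p)) {
    fail <- stats::runif(n_probes * n) < detection_fail_rate
    detection_p[fail] <- stats::runif(sum(fail), 0.002, 0.8)
  }
  if (missing_rate > 0 && length(beta)) {
    beta[stats::runif(n_probes * n) < missing_rate] <- NA_real_
  }

  truth <- if (is.null(spikes)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               delta_beta = numeric(0))
  } else {
    as.data.frame(spikes)
  }
  list(
    dataset = meth_set(beta, manifest, sheet, detection_p),
    truth = truth,
    celltype_proportions = W
  )
}
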