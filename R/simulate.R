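#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators.  The defaults
#' emulate the study conditions of the surgical cohort the package models:
#' 17 donors contributing 28 cervical discs (1-3 discs per donor), AF/NP
#' clear rates of about 61%/57%, an overall severe-degeneration rate of
#' 38%, an expression compendium of 11 AF + 9 NP chips with a small
#' fraction of planted differentially expressed genes — AF-up genes as
#' on/off patterns (undetectable in NP, fold-change lognormal with median
#' 10) and NP-up genes as moderate shifts (median fold-change 4, detected
#' in both tissues) — 11 probes per probe set with lognormal signal noise,
#' and triplicate qPCR measurements with 0.15-cycle noise at efficiency 2.
#'
#' @param seed integer RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param n_donors,discs_per_donor_probs score-sheet cohort shape
#'   (probabilities of a donor contributing 1, 2 or 3 discs).
#' @param p_clear named probabilities (AF, NP) of a sample passing the
#'   tissue-identity gate.
#' @param p_severe probability of severe cellular degeneration.
#' @param age_range,mri_grades donor age span and admissible MRI grades.
#' @param n_genes,n_af,n_np,n_af_up,n_np_up expression matrix shape and
#'   planted DEG counts.
#' @param af_fc_median,np_fc_median,fc_sdlog lognormal fold-change
#'   distributions of the planted genes.
#' @param noise_sigma lognormal sigma of chip signal noise.
#' @param probe_affinity_sdlog lognormal sigma of fixed per-probe
#'   affinities (cancel in pairwise chip ratios).
#' @param probes_per_set probes per probe set.
#' @param detection_floor detection noise floor on the linear signal scale.
#' @param base_meanlog,base_sdlog lognormal distribution of baseline gene
#'   signal means.
#' @param qpcr_sigma_cq,qpcr_sigma_bio technical replicate noise (cycles)
#'   and optional between-sample biological scatter (lognormal sigma,
#'   default 0: the marker's group mean maps deterministically to Cq).
#' @param qpcr_efficiency,qpcr_ref_cq assay efficiency and the Cq a
#'   reference-level abundance maps to.
#' @param qpcr_n_af,qpcr_n_np clear test samples per group in the qPCR
#'   generator.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_donors = 17,
                       discs_per_donor_probs = c(9, 5, 3) / 17,
                       p_clear = c(AF = 0.61, NP = 0.57),
                       p_severe = 0.38,
                       age_range = c(36, 77),
                       mri_grades = 3:4,
                       n_genes = 1000, n_af = 11, n_np = 9,
                       n_af_up = 50, n_np_up = 20,
                       af_fc_median = 10, np_fc_median = 4, fc_sdlog = 0.25,
                       noise_sigma = 0.25, probe_affinity_sdlog = 0.3,
                       probes_per_set = 11, detection_floor = 100,
                       base_meanlog = log(500), base_sdlog = 1,
                       qpcr_sigma_cq = 0.15, qpcr_sigma_bio = 0,
                       qpcr_efficiency = 2.0, qpcr_ref_cq = 20,
                       qpcr_n_af = 9, qpcr_n_np = 5) {
  if (abs(sum(discs_per_donor_probs) - 1) > 1e-8)
    stop("discs_per_donor_probs must sum to 1", call. = FALSE)
  if (any(c(p_clear, p_severe) < 0) || any(c(p_clear, p_severe) > 1))
    stop("quality-mix probabilities must lie in [0, 1]", call. = FALSE)
  if (n_af_up + n_np_up > n_genes)
    stop("planted DEG counts exceed n_genes", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# draw one IVD item-grade vector for a given latent tier (rejection
# sampling against the tier's defining decision rule)
draw_ivd_items <- function(clear) {
  repeat {
    items <- if (clear) sample(1:2, 6, replace = TRUE, prob = c(0.4, 0.6))
             else sample(0:2, 6, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    sc <- score_rubric(items, "IVD")
    if (clear == (sc$total > 6 && !sc$flag)) return(items)
  }
}

draw_dd_items <- function(severe) {
  repeat {
    items <- if (severe) sample(0:2, 3, replace = TRUE, prob = c(0.2, 0.4, 0.4))
             else sample(0:1, 3, replace = TRUE, prob = c(0.45, 0.55))
    sc <- score_rubric(items, "DD")
    if (severe == (sc$total > 3 || sc$flag)) return(items)
  }
}

#' Simulate a score-sheet cohort
#'
#' Draws donors (gender, age, number of discs), per-disc metadata (level,
#' MRI grade) and, for each sample and compartment, a latent quality tier
#' (clear/unclear tissue identity, mild/severe degeneration) from the
#' configured mix; item grades are then drawn consistently with the tier.
#'
#' @param config a [sim_config()].
#' @return list with `records` (item-level score sheet, totals and flags
#'   included) and `truth` (per-sample latent tiers).
#' @export
simulate_score_sheet <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    donors <- data.frame(
      donor_id = seq_len(config$n_donors),
      gender = sample(c("f", "m"), config$n_donors, replace = TRUE),
      age = sample(seq(config$age_range[1], config$age_range[2]),
                   config$n_donors, replace = TRUE),
      n_discs = sample(seq_along(config$discs_per_donor_probs),
                       config$n_donors, replace = TRUE,
                       prob = config$discs_per_donor_probs)
    )
    levels_pool <- c("C3/4", "C4/5", "C5/6", "C6/7")
    rows <- list()
    truth <- list()
    sid <- 0L
    for (d in seq_len(nrow(donors))) {
      lv <- sample(levels_pool, donors$n_discs[d])
      for (k in seq_len(donors$n_discs[d])) {
        sid <- sid + 1L
        mri <- sample(config$mri_grades, 1)
        for (comp in c("AF", "NP")) {
          clear <- runif(1) < config$p_clear[[comp]]
          severe <- runif(1) < config$p_severe
          ivd <- draw_ivd_items(clear)
          dd <- draw_dd_items(severe)
          si <- score_rubric(ivd, "IVD")
          sd_ <- score_rubric(dd, "DD")
          rows[[length(rows) + 1L]] <- data.frame(
            donor_id = donors$donor_id[d], gender = donors$gender[d],
            age = donors$age[d], sample_id = sid, disc_level = lv[k],
            mri_grade = mri, compartment = comp,
            ivd_i1 = ivd[1], ivd_i2 = ivd[2], ivd_i3 = ivd[3],
            ivd_i4 = ivd[4], ivd_i5 = ivd[5], ivd_i6 = ivd[6],
            dd_i1 = dd[1], dd_i2 = dd[2], dd_i3 = dd[3],
            ivd_total = si$total, ivd_any_zero = si$flag,
            dd_total = sd_$total, dd_any_two = sd_$flag,
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, compartment = comp,
            tier_clear = clear, tier_severe = severe,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate a probe-level expression matrix with planted DEGs
#'
#' Null genes share one mean across both tissues; AF-up genes follow an
#' on/off pattern (NP mean pinned well below the detection floor, AF mean
#' = planted fold-change times the NP level); NP-up genes are moderate
#' shifts on a baseline kept comfortably above the floor so the gene stays
#' detected in both tissues.  Probe-level signals multiply the group mean
#' by a fixed per-probe affinity and lognormal chip noise; per-chip
#' summary signals are 20% trimmed means over probes, and detection calls
#' come from the configured floor.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (per-gene label `AF_up`/`NP_up`/`null` and planted fold-change).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    g <- config$n_genes
    genes <- sprintf("G%04d", seq_len(g))
    label <- rep("null", g)
    planted <- sample(g, config$n_af_up + config$n_np_up)
    label[planted[seq_len(config$n_af_up)]] <- "AF_up"
    label[planted[config$n_af_up + seq_len(config$n_np_up)]] <- "NP_up"
    fc <- rep(1, g)
    fc[label == "AF_up"] <- rlnorm(config$n_af_up,
                                   log(config$af_fc_median), config$fc_sdlog)
    fc[label == "NP_up"] <- rlnorm(config$n_np_up,
                                   log(config$np_fc_median), config$fc_sdlog)
    base <- rlnorm(g, config$base_meanlog, config$base_sdlog)
    mean_af <- base
    mean_np <- base
    off_level <- config$detection_floor / 4    # pinned below the floor
    mean_np[label == "AF_up"] <- off_level
    mean_af[label == "AF_up"] <- off_level * fc[label == "AF_up"]
    stable <- pmax(base[label == "NP_up"], 2.5 * config$detection_floor)
    mean_af[label == "NP_up"] <- stable
    mean_np[label == "NP_up"] <- stable * fc[label == "NP_up"]
    n_chips <- config$n_af + config$n_np
    group <- rep(c("AF", "NP"), c(config$n_af, config$n_np))
    chips <- paste0(group, c(seq_len(config$n_af), seq_len(config$n_np)))
    p <- config$probes_per_set
    affinity <- matrix(rlnorm(g * p, 0, config$probe_affinity_sdlog), g, p)
    probe <- array(NA_real_, dim = c(g, n_chips, p),
                   dimnames = list(genes, chips, paste0("p", seq_len(p))))
    for (j in seq_len(n_chips)) {
      mu <- if (group[j] == "AF") mean_af else mean_np
      noise <- matrix(exp(rnorm(g * p, 0, config$noise_sigma)), g, p)
      probe[, j, ] <- mu * affinity * noise
    }
    em <- expression_matrix(signal = NULL, group = group,
                            probe_signals = probe,
                            detection_floor = config$detection_floor)
    list(matrix = em,
         truth = data.frame(gene_id = genes, label = label, fc = fc,
                            stringsAsFactors = FALSE))
  })
}

#' Default marker-level ground truth for the qPCR generator
#'
#' AF markers are AF-exclusive (NP abundance 0, i.e. no amplification);
#' NP markers are expressed in both tissues with the configured NP-up
#' fold-change.  Abundances are on the relative scale of the reference
#' genes.
#'
#' @param config a [sim_config()].
#' @param panel a [marker_panel()].
#' @return data frame `gene_id`, `mean_af`, `mean_np`, `planted_fc`.
#' @export
marker_truth <- function(config = sim_config(), panel = marker_panel()) {
  with_seed(config$seed + 2L, {
    n_af_m <- length(panel$af_markers)
    n_np_m <- length(panel$np_markers)
    af_level <- rlnorm(n_af_m, log(0.1), 0.5)
    np_base <- rlnorm(n_np_m, log(0.05), 0.5)
    np_fc <- rlnorm(n_np_m, log(config$np_fc_median), config$fc_sdlog)
    rbind(
      data.frame(gene_id = panel$af_markers, mean_af = af_level,
                 mean_np = 0, planted_fc = Inf, stringsAsFactors = FALSE),
      data.frame(gene_id = panel$np_markers, mean_af = np_base,
                 mean_np = np_base * np_fc, planted_fc = np_fc,
                 stringsAsFactors = FALSE))
  })
}

#' Simulate a triplicate qPCR Cq table
#'
#' Per sample and marker, the underlying abundance is the marker's group
#' mean (times optional lognormal biological scatter when
#' `qpcr_sigma_bio > 0`); the quantification cycle is
#' \eqn{Cq = -\log_E(\mathrm{abundance}) + Cq_{ref}} plus Gaussian
#' technical noise per replicate.  Markers with zero abundance in a
#' tissue never amplify there (all replicates blank).  Reference genes sit
#' at abundance 1.  A per-sample loading shift is added to every assay of
#' the sample and cancels in normalisation.
#'
#' @param config a [sim_config()].
#' @param truth marker-level truth as from [marker_truth()].
#' @return list with `cq_table` (long triplicate table), `assays`
#'   ([qpcr_assays()]), `groups` (sample to group map) and `truth`.
#' @export
simulate_qpcr <- function(config = sim_config(),
                          truth = marker_truth(config)) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    e <- config$qpcr_efficiency
    samples <- c(paste0("AF", seq_len(config$qpcr_n_af)),
                 paste0("NP", seq_len(config$qpcr_n_np)))
    groups <- setNames(rep(c("AF", "NP"),
                           c(config$qpcr_n_af, config$qpcr_n_np)), samples)
    genes <- c(truth$gene_id, "ATP5F1B", "RPL13A")
    rows <- list()
    for (s in samples) {
      shift <- rnorm(1, 0, 0.5)     # loading offset, cancels on refs
      for (g in genes) {
        if (g %in% truth$gene_id) {
          mu <- if (groups[[s]] == "AF") truth$mean_af[truth$gene_id == g]
                else truth$mean_np[truth$gene_id == g]
          if (mu > 0 && config$qpcr_sigma_bio > 0)
            mu <- mu * rlnorm(1, 0, config$qpcr_sigma_bio)
        } else mu <- 1
        if (mu == 0) {
          reps <- rep(NA_real_, 3)  # no amplification
        } else {
          cq0 <- -log(mu) / log(e) + config$qpcr_ref_cq + shift
          reps <- cq0 + rnorm(3, 0, config$qpcr_sigma_cq)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene_id = g,
          cq1 = reps[1], cq2 = reps[2], cq3 = reps[3],
          stringsAsFactors = FALSE)
      }
    }
    assays <- qpcr_assays(genes, efficiency = e)
    list(cq_table = do.call(rbind, rows), assays = assays,
         groups = groups, truth = truth)
  })
}
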