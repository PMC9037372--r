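#' Configuration for the synthetic exLR cohort generator
#'
#' Default values emulate a three-cohort plasma exLR profiling study:
#' 72 CRC, 42 CRA and 80 healthy samples over ~15,000 long-RNA genes
#' (roughly 70% protein-coding, 25% lncRNA, the rest pseudogene/other),
#' negative-binomial counts (variance \eqn{\mu + \phi\mu^2}, dispersion
#' 0.2 — typical bulk-RNA overdispersion), log-normal baseline abundances,
#' per-sample library sizes, a planted set of CRC-upregulated genes with
#' log2 fold changes in `log2fc_range` (CRA receives half the effect on the
#' log scale by default, giving the monotone healthy < CRA < CRC trend),
#' random dropout zeros, and exponential survival times for CRC samples
#' with censoring.
#'
#' @param n_genes number of genes.
#' @param biotype_fractions named simplex over
#'   protein_coding/lncRNA/pseudogene/other.
#' @param n_crc,n_cra,n_healthy cohort sizes.
#' @param n_planted_up number of planted CRC-upregulated genes (among
#'   protein-coding/lncRNA genes).
#' @param log2fc_range range of true log2 fold changes for planted genes.
#' @param cra_effect fraction of the planted log2 effect expressed in CRA.
#' @param nb_dispersion negative-binomial dispersion \eqn{\phi}.
#' @param library_size_range per-sample total expected long-RNA read count.
#' @param gene_length_range union-exon length range in bp.
#' @param dropout_rate probability that an observed count is zeroed.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance.
#' @param survival list: `baseline_hazard` (events/month),
#'   `hr_per_sd` (hazard ratio per SD of the latent score),
#'   `censor_rate` (target censoring fraction).
#' @param seed integer seed controlling all randomness.
#' @return validated list of class `exlr_sim_config`.
#' @export
simulation_config <- function(n_genes = 15000,
                              biotype_fractions = c(protein_coding = 0.70,
                                                    lncRNA = 0.25,
                                                    pseudogene = 0.04,
                                                    other = 0.01),
                              n_crc = 72, n_cra = 42, n_healthy = 80,
                              n_planted_up = 20,
                              log2fc_range = c(1.0, 2.0),
                              cra_effect = 0.5,
                              nb_dispersion = 0.2,
                              library_size_range = c(1e6, 2e6),
                              gene_length_range = c(200L, 10000L),
                              dropout_rate = 0.005,
                              baseline_meanlog = 1.5,
                              baseline_sdlog = 2.2,
                              survival = list(baseline_hazard = 0.03,
                                              hr_per_sd = 2.0,
                                              censor_rate = 0.3),
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    biotype_fractions = biotype_fractions,
    n_crc = as.integer(n_crc), n_cra = as.integer(n_cra),
    n_healthy = as.integer(n_healthy),
    n_planted_up = as.integer(n_planted_up),
    log2fc_range = log2fc_range,
    cra_effect = cra_effect,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    gene_length_range = as.integer(gene_length_range),
    dropout_rate = dropout_rate,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    survival = survival,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 10) abort("n_genes too small.")
  if (abs(sum(biotype_fractions) - 1) > 1e-8 || any(biotype_fractions < 0)) {
    abort("biotype_fractions must be a simplex.")
  }
  if (!setequal(names(biotype_fractions), BIOTYPE_LEVELS)) {
    abort("biotype_fractions must name protein_coding, lncRNA, pseudogene, other.")
  }
  if (cfg$n_planted_up > cfg$n_genes) abort("more planted genes than genes.")
  for (rng in list(cfg$log2fc_range, cfg$library_size_range,
                   cfg$gene_length_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) abort("malformed range in config.")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1).")
  }
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be positive.")
  if (cfg$survival$hr_per_sd <= 0) abort("hr_per_sd must be positive.")
  structure(cfg, class = "exlr_sim_config")
}

#' Simulate a three-cohort exLR study with ground truth
#'
#' Draws baseline gene abundances once, plants CRC-upregulated genes
#' (partially expressed in CRA), and samples negative-binomial counts whose
#' expected value is proportional to abundance times gene length, scaled to
#' the sample's library size — so downstream TPM recovers the planted
#' abundance ratios. CRC samples additionally receive survival endpoints
#' tied to a latent prognostic score via [simulate_survival()]. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg an [simulation_config()] object.
#' @return list with `counts` (an [exlr_matrix()]), `annotation`, `design`,
#'   and `truth` (list: `planted` tibble of gene_id/true_log2fc,
#'   `latent_score` named vector over CRC samples, `hr_per_sd`, `config`).
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "exlr_sim_config")) abort("cfg must be a simulation_config().")
  withr::with_seed(cfg$seed, {
    g <- cfg$n_genes
    biotype <- sample(names(cfg$biotype_fractions), g, replace = TRUE,
                      prob = cfg$biotype_fractions)
    gene_id <- sprintf("SIMG%05d.%d", seq_len(g), sample(1:9, g, TRUE))
    annotation <- tibble(
      gene_id = gene_id,
      symbol = sprintf("Gene%05d", seq_len(g)),
      biotype = biotype,
      length_bp = as.integer(round(runif(g, cfg$gene_length_range[1],
                                         cfg$gene_length_range[2])))
    )
    base_abund <- rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)

    long_rna <- which(biotype %in% LONG_RNA_BIOTYPES)
    if (cfg$n_planted_up > length(long_rna)) {
      abort("not enough long-RNA genes to plant effects in.")
    }
    planted_idx <- sort(sample(long_rna, cfg$n_planted_up))
    true_lfc <- runif(cfg$n_planted_up, cfg$log2fc_range[1],
                      cfg$log2fc_range[2])

    n_tot <- cfg$n_crc + cfg$n_cra + cfg$n_healthy
    cohort <- rep(c("CRC", "CRA", "healthy"),
                  c(cfg$n_crc, cfg$n_cra, cfg$n_healthy))
    sample_id <- sprintf("%s%03d", c(CRC = "CRC", CRA = "CRA",
                                     healthy = "HLT")[cohort], seq_len(n_tot))
    lib_size <- runif(n_tot, cfg$library_size_range[1],
                      cfg$library_size_range[2])

    # per-cohort abundance with planted effects
    fold_for <- function(coh) {
      f <- rep(1, g)
      mult <- switch(coh, CRC = 1, CRA = cfg$cra_effect, healthy = 0)
      f[planted_idx] <- 2^(true_lfc * mult)
      f
    }
    counts <- matrix(0L, g, n_tot, dimnames = list(gene_id, sample_id))
    size <- 1 / cfg$nb_dispersion
    for (j in seq_len(n_tot)) {
      ab <- base_abund * fold_for(cohort[j])
      rate <- ab * annotation$length_bp
      mu <- lib_size[j] * rate / sum(rate)
      counts[, j] <- rnbinom(g, size = size, mu = mu)
    }
    if (cfg$dropout_rate > 0) {
      drop <- matrix(rbinom(g * n_tot, 1, cfg$dropout_rate) == 1, g, n_tot)
      counts[drop] <- 0L
    }
    storage.mode(counts) <- "integer"

    design <- tibble(
      sample_id = sample_id,
      cohort = cohort,
      stage = ifelse(cohort == "CRC",
                     sample(c("I", "II", "III", "IV"), n_tot, replace = TRUE,
                            prob = c(22, 31, 3, 16) / 72),
                     NA_character_),
      cea_status = ifelse(cohort == "CRC",
                          sample(c("negative", "positive"), n_tot,
                                 replace = TRUE, prob = c(0.6, 0.4)),
                          NA_character_)
    )
    latent <- rnorm(cfg$n_crc)
    names(latent) <- sample_id[cohort == "CRC"]
    design <- simulate_survival(design, latent,
                                hr_per_sd = cfg$survival$hr_per_sd,
                                censor_rate = cfg$survival$censor_rate,
                                baseline_hazard = cfg$survival$baseline_hazard,
                                seed = cfg$seed + 1L)

    list(
      counts = exlr_matrix(counts, unit = "counts"),
      annotation = annotation,
      design = design,
      truth = list(
        planted = tibble(gene_id = gene_id[planted_idx],
                         true_log2fc = true_lfc,
                         biotype = biotype[planted_idx]),
        latent_score = latent,
        hr_per_sd = cfg$survival$hr_per_sd,
        config = cfg
      )
    )
  })
}

#' Attach simulated survival endpoints to CRC samples
#'
#' Event times are exponential with log-hazard linear in the standardized
#' score: \eqn{\lambda_i = \lambda_0 \exp(\log(HR) \cdot z_i)}. Independent
#' uniform censoring times are drawn on `(0, u)`, with `u` solved
#' numerically so the expected censoring fraction matches `censor_rate`.
#' OS and DFS both follow this model (DFS with a 1.5x hazard, so recurrence
#' precedes death on average). Non-CRC samples get `NA` endpoints.
#'
#' @param design design tibble.
#' @param scores named numeric vector over CRC sample IDs.
#' @param hr_per_sd hazard ratio per standard deviation of score (> 0).
#' @param censor_rate target fraction censored, in `[0, 1)`.
#' @param baseline_hazard events per month at score 0.
#' @param seed integer seed.
#' @return `design` with `os_time`, `os_event`, `dfs_time`, `dfs_event`.
#' @export
simulate_survival <- function(design, scores, hr_per_sd = 2.0,
                              censor_rate = 0.3, baseline_hazard = 0.03,
                              seed = 1L) {
  design <- validate_design(design)
  if (hr_per_sd <= 0) abort("hr_per_sd must be positive.")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate in [0, 1).")
  crc_ids <- design$sample_id[design$cohort == "CRC"]
  if (!length(crc_ids)) abort("no CRC samples to simulate survival for.")
  missing <- setdiff(crc_ids, names(scores))
  if (length(missing)) abort("scores missing for some CRC samples.")
  z <- scores[crc_ids]
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  lambda <- baseline_hazard * exp(log(hr_per_sd) * z)
  withr::with_seed(seed, {
    draw <- function(rates) {
      t_event <- rexp(length(rates), rate = rates)
      if (censor_rate == 0) {
        list(time = t_event, event = rep(TRUE, length(rates)))
      } else {
        u <- censor_uniform_bound(rates, censor_rate)
        t_cens <- runif(length(rates), 0, u)
        list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
      }
    }
    os <- draw(lambda)
    dfs <- draw(lambda * 1.5)
    for (cols in list(c("os_time", "os_event"), c("dfs_time", "dfs_event"))) {
      design[[cols[1]]] <- NA_real_
      design[[cols[2]]] <- NA
    }
    idx <- match(crc_ids, design$sample_id)
    design$os_time[idx] <- os$time
    design$os_event[idx] <- os$event
    design$dfs_time[idx] <- dfs$time
    design$dfs_event[idx] <- dfs$event
    design
  })
}

# expected censoring fraction for C ~ U(0, u), T_i ~ Exp(rate_i):
#   P(C < T_i) = (1 - exp(-rate_i * u)) / (rate_i * u)
# decreasing in u: -> 1 as u -> 0 (immediate censoring), -> 0 as u -> Inf
censor_uniform_bound <- function(rates, target) {
  frac <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
  uniroot(frac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Build gene-set fixtures around the simulation truth
#'
#' Produces `n_sets` gene sets of size `set_size`: the first `n_signal_sets`
#' draw a fraction `signal_fraction` of their members from the planted DE
#' genes (the rest uniformly from unplanted genes); the remaining sets are
#' fully random. The manifest records which sets carry signal.
#'
#' @param truth `truth` element from [simulate_cohort()].
#' @param all_genes character vector of all gene IDs in the cohort.
#' @param n_sets,set_size number and size of the sets.
#' @param signal_fraction fraction of planted members in signal sets.
#' @param n_signal_sets how many sets carry signal (default half).
#' @param seed integer seed.
#' @return list with `sets` (named list) and `manifest` (tibble `set`,
#'   `signal`).
#' @export
make_gene_sets <- function(truth, all_genes, n_sets = 10, set_size = 25,
                           signal_fraction = 0.8,
                           n_signal_sets = floor(n_sets / 2), seed = 1L) {
  if (set_size > length(all_genes)) abort("set_size exceeds gene count.")
  planted <- truth$planted$gene_id
  background <- setdiff(all_genes, planted)
  withr::with_seed(seed, {
    sets <- list()
    signal <- logical(n_sets)
    for (i in seq_len(n_sets)) {
      nm <- sprintf("SET%02d", i)
      if (i <= n_signal_sets && length(planted)) {
        n_sig <- min(round(signal_fraction * set_size), length(planted))
        members <- c(sample(planted, n_sig),
                     sample(background, set_size - n_sig))
        signal[i] <- TRUE
      } else {
        members <- sample(background, set_size)
      }
      sets[[nm]] <- sort(members)
    }
    list(sets = sets,
         manifest = tibble(set = names(sets), signal = signal))
  })
}
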