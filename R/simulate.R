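#' True marker-gene decay trajectory
#'
#' Evaluates the ground-truth concentration of a marker gene over the
#' sampling days of a configured experiment. Donor (`dsRed`) and plasmid
#' (`gfp`) genes follow a piecewise log-linear (biphasic) curve: log10
#' concentration falls with slope `-1/phase1_d_value` up to and including
#' `breakpoint_day`, then either continues at `-1/phase2_d_value` or — if a
#' rebound rate is configured for the treatment — rises at
#' `+rebound[[treatment]]` log10/day. The `16S` gene (total bacteria) is
#' constant at `total_16s_c0`.
#'
#' @param cfg A [synthetic_config()].
#' @param treatment Treatment label present in `cfg$treatments`.
#' @param gene One of `"dsRed"`, `"gfp"`, `"16S"`.
#' @param days Days at which to evaluate; defaults to `cfg$sampling_days`.
#' @return A data frame with columns `treatment`, `gene`, `day`,
#'   `concentration` (copies/g dry weight, positive everywhere).
#' @examples
#' cfg <- synthetic_config()
#' simulate_decay_trajectory(cfg, "CT", "gfp")
#' @export
simulate_decay_trajectory <- function(cfg, treatment, gene,
                                      days = cfg$sampling_days) {
  validate_config(cfg)
  if (!treatment %in% cfg$treatments)
    stop_values("unknown treatment '%s'", treatment)
  if (!gene %in% c("dsRed", "gfp", "16S"))
    stop_values("unknown gene '%s'", gene)
  c0 <- switch(gene, dsRed = cfg$donor_c0, gfp = cfg$plasmid_c0,
               `16S` = cfg$total_16s_c0)
  if (gene == "16S") {
    conc <- rep(c0, length(days))
  } else {
    bp <- cfg$breakpoint_day
    s1 <- -1 / cfg$phase1_d_value
    reb <- cfg$rebound[[treatment]]
    s2 <- if (!is.null(reb) && reb > 0) reb else -1 / cfg$phase2_d_value
    log10c <- log10(c0) +
      ifelse(days <= bp, s1 * days, s1 * bp + s2 * (days - bp))
    conc <- 10 ^ log10c
  }
  data.frame(treatment = treatment, gene = gene, day = days,
             concentration = conc, stringsAsFactors = FALSE)
}

#' Simulate one ddPCR measurement
#'
#' Poisson droplet-occupancy model of droplet digital PCR: at per-microlitre
#' template concentration lambda, each of `n_droplets` droplets of volume `v`
#' microlitres is positive independently with probability
#' `1 - exp(-lambda * v)`. The concentration estimate inverts the observed
#' positive fraction `p_hat`: `lambda_hat = -log(1 - p_hat) / v`, rescaled
#' back to copies per gram dry weight.
#'
#' With `dilution_to_droplet = "auto"` (the default) each measurement is
#' diluted so the expected droplet occupancy is 0.3, mimicking the standard
#' laboratory practice of keeping reactions inside the quantifiable range;
#' the factor used is returned. Saturated reactions (all droplets positive)
#' are flagged `"saturated"` and return `NA`; reactions with zero positive
#' droplets are flagged `"below_detection"` and return 0.
#'
#' @param true_concentration True concentration, copies/g dry weight (> 0).
#' @param cfg A [synthetic_config()] supplying droplet parameters.
#' @param seed Optional integer; when given, the draw is made under a local
#'   RNG seeded with it (the caller's RNG state is untouched).
#' @return A one-row data frame: `n_pos_droplets`, `n_total_droplets`,
#'   `estimate` (copies/g DW), `dilution` (copies/g DW to copies/uL factor),
#'   `flag` (`"ok"`, `"below_detection"` or `"saturated"`).
#' @examples
#' cfg <- synthetic_config()
#' simulate_ddpcr(1e6, cfg, seed = 42)
#' @export
simulate_ddpcr <- function(true_concentration, cfg, seed = NULL) {
  if (!is.numeric(true_concentration) || true_concentration <= 0)
    stop_values("true_concentration must be > 0")
  draw <- function() {
    v <- cfg$ddpcr_droplet_volume
    n <- cfg$ddpcr_n_droplets
    dil <- cfg$dilution_to_droplet
    if (identical(dil, "auto")) {
      # dilute so that lambda * v = -log(1 - 0.3)
      target_lambda <- -log(1 - 0.3) / v
      dil <- target_lambda / true_concentration
    }
    lambda <- true_concentration * dil
    p <- 1 - exp(-lambda * v)
    n_pos <- stats::rbinom(1L, n, p)
    p_hat <- n_pos / n
    if (n_pos == 0L) {
      est <- 0; flag <- "below_detection"
    } else if (n_pos == n) {
      est <- NA_real_; flag <- "saturated"
    } else {
      est <- (-log(1 - p_hat) / v) / dil; flag <- "ok"
    }
    data.frame(n_pos_droplets = n_pos, n_total_droplets = n,
               estimate = est, dilution = dil, flag = flag,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate sorted transconjugant OTU tables
#'
#' Draws one Dirichlet-multinomial community per sample around the per-group
#' expected composition in `cfg$community_template`: sample proportions are
#' Dirichlet with concentration `dm_concentration * template`, and counts are
#' multinomial at `seq_depth` reads, so every column sums exactly to the
#' sequencing depth. Samples are the five groups (shared raw material `IP`
#' plus treatment x phase combinations present in the template) times
#' `n_replicates`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return An [otu_table()] with counts, taxonomy and sample metadata.
#' @export
simulate_transconjugant_table <- function(cfg, seed = cfg$seed) {
  validate_config(cfg)
  tpl <- cfg$community_template
  groups <- unique(tpl$group)
  pool <- unique(tpl[, c("phylum", "family", "genus", "otu_id")])
  pool <- pool[order(pool$otu_id), ]
  otu_ids <- pool$otu_id
  with_seed(seed, {
    samples <- list()
    meta <- list()
    for (grp in groups) {
      sub <- tpl[tpl$group == grp, ]
      p <- numeric(length(otu_ids))
      names(p) <- otu_ids
      p[sub$otu_id] <- sub$prop
      alpha <- cfg$dm_concentration * p
      for (r in seq_len(cfg$n_replicates)) {
        q <- rdirichlet1(alpha)
        counts <- stats::rmultinom(1L, size = cfg$seq_depth, prob = q)[, 1]
        sid <- sprintf("%s_%d", gsub("-", "_", grp), r)
        samples[[sid]] <- counts
        trt <- if (grepl("-", grp)) sub("-.*$", "", grp) else NA_character_
        phs <- if (grepl("-", grp)) sub("^.*-", "", grp) else grp
        meta[[sid]] <- data.frame(sample_id = sid, group = grp,
                                  treatment = trt, phase = phs, replicate = r,
                                  stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, samples)
    rownames(counts) <- otu_ids
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    taxonomy <- make_taxonomy(pool)
    otu_table(counts, taxonomy, metadata)
  })
}

# Build a six-rank lineage table from the OTU pool. OTUs whose template genus
# is a rank-prefixed label (e.g. "f__Bacillaceae") are recorded as
# unclassified at genus level; aggregate_taxonomy() restores the prefixed
# label so host-range sets can include them.
make_taxonomy <- function(pool) {
  genus <- ifelse(grepl("^f__", pool$genus), "unclassified", pool$genus)
  data.frame(
    otu_id = pool$otu_id,
    domain = "Bacteria",
    phylum = pool$phylum,
    class = paste0(pool$phylum, "_cl"),
    order = paste0(pool$family, "_or"),
    family = pool$family,
    genus = genus,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete composting experiment
#'
#' Generates everything the analysis pipeline consumes, together with the
#' ground truth needed to test recovery:
#' \itemize{
#'   \item an abundance table with one ddPCR observation per
#'     (treatment, replicate, day, gene) — true trajectory values are
#'     perturbed by replicate-level lognormal noise (`bio_sd_log10`) and then
#'     observed through the droplet counting model;
#'   \item a sorted transconjugant OTU table (Dirichlet-multinomial);
#'   \item the ground truth: true trajectories, true phase D-values, the true
#'     spread potential per treatment and day, and the community template.
#' }
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `compost_experiment` with elements `abundance`
#'   (data frame), `otu` ([otu_table()]), `truth` (list) and `config`.
#' @examples
#' cfg <- synthetic_config(n_replicates = 2, seq_depth = 2000,
#'                         ddpcr_n_droplets = 5000)
#' exp <- make_experiment(cfg)
#' head(exp$abundance)
#' @export
make_experiment <- function(cfg) {
  validate_config(cfg)
  genes <- c("dsRed", "gfp", "16S")
  traj <- do.call(rbind, lapply(cfg$treatments, function(tr) {
    do.call(rbind, lapply(genes, function(g)
      simulate_decay_trajectory(cfg, tr, g)))
  }))
  abundance <- with_seed(cfg$seed, {
    rows <- list()
    for (tr in cfg$treatments) {
      for (r in seq_len(cfg$n_replicates)) {
        for (d in cfg$sampling_days) {
          for (g in genes) {
            true_c <- traj$concentration[traj$treatment == tr &
                                         traj$gene == g & traj$day == d]
            obs_c <- true_c * 10 ^ stats::rnorm(1L, 0, cfg$bio_sd_log10)
            dd <- simulate_ddpcr(obs_c, cfg)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sprintf("%s_r%d_d%g", tr, r, d),
              treatment = tr, replicate = r, day = d,
              phase = assign_phase(d, tr, cfg), gene = g,
              copies_per_g_dw = dd$estimate,
              n_pos_droplets = dd$n_pos_droplets,
              n_total_droplets = dd$n_total_droplets,
              flag = dd$flag, stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  otu <- simulate_transconjugant_table(cfg, seed = cfg$seed + 1L)

  # ground-truth spread potential per treatment/day from true trajectories
  sp_true <- do.call(rbind, lapply(cfg$treatments, function(tr) {
    sub <- traj[traj$treatment == tr, ]
    wide <- stats::reshape(sub, idvar = "day", timevar = "gene",
                           direction = "wide", v.names = "concentration")
    sp <- spread_potential(wide$concentration.gfp, wide$concentration.dsRed,
                           wide$concentration.16S)
    data.frame(treatment = tr, day = wide$day, sp = sp$sp,
               stringsAsFactors = FALSE)
  }))
  true_d <- do.call(rbind, lapply(cfg$treatments, function(tr) {
    reb <- cfg$rebound[[tr]]
    d2 <- if (!is.null(reb) && reb > 0) Inf else cfg$phase2_d_value
    data.frame(treatment = tr, phase1_d = cfg$phase1_d_value, phase2_d = d2,
               rebound_rate = reb %||% 0, stringsAsFactors = FALSE)
  }))
  structure(list(
    abundance = abundance,
    otu = otu,
    truth = list(trajectories = traj, d_values = true_d, sp = sp_true,
                 community_template = cfg$community_template),
    config = cfg
  ), class = "compost_experiment")
}

#' @export
print.compost_experiment <- function(x, ...) {
  cat(sprintf(
    "Simulated composting experiment: %d abundance records, %d OTUs x %d samples\n",
    nrow(x$abundance), nrow(x$otu$counts), ncol(x$otu$counts)))
  invisible(x)
}
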