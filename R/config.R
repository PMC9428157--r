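#' Configuration for a simulated composting experiment
#'
#' Builds and validates the full parameterization of a simulated composting
#' run: two treatments (normal thermophilic, `NT`, and continuous
#' thermophilic, `CT`) followed over a shared sampling-day grid, with
#' piecewise log-linear decay of the donor (`dsRed`) and plasmid (`gfp`)
#' marker genes, droplet digital PCR (ddPCR) observation noise, and
#' Dirichlet-multinomial transconjugant communities per composting phase.
#'
#' Decay is biphasic: log10 concentration falls with slope
#' `-1/phase1_d_value` up to `breakpoint_day` (the breakpoint day belongs to
#' phase I) and with slope `-1/phase2_d_value` afterwards, unless a rebound
#' rate is configured for a treatment, in which case the phase-II slope is
#' `+rebound[[treatment]]` log10 units per day. The total bacterial pool
#' (16S rRNA gene copies) is held constant at `total_16s_c0`.
#'
#' The defaults encode the study conditions the package targets: donor and
#' plasmid starting concentrations of 3.30e6 and 1.04e7 copies/g dry weight,
#' a phase-I D-value of 7.0 days with breakpoint at day 15, a slight
#' maturation-phase rebound in NT only, and a flat 16S pool of 7.264747e10
#' copies/g chosen so that the ground-truth spread potential starts at
#' 3.91e-4 and, under the CT phase-II D-value of 563 days, ends at 2.54e-6
#' transconjugants per recipient on day 40.
#'
#' @param treatments Character vector of treatment labels.
#' @param sampling_days Strictly increasing numeric vector of sampling days,
#'   starting at 0.
#' @param n_replicates Number of replicate composting reactors per treatment.
#' @param donor_c0,plasmid_c0,total_16s_c0 Initial concentrations
#'   (copies per gram dry weight) of the dsRed, gfp and 16S rRNA markers.
#' @param phase1_d_value Phase-I decimal reduction time (days per log10 drop).
#' @param phase2_d_value Phase-II decimal reduction time; `Inf` means no
#'   phase-II decay.
#' @param breakpoint_day Day separating the fast and slow decay phases.
#' @param rebound Named list (one entry per treatment) of phase-II rebound
#'   rates in log10 units per day; 0 disables the rebound and the treatment
#'   follows `phase2_d_value` instead.
#' @param ddpcr_n_droplets Droplets generated per ddPCR reaction.
#' @param ddpcr_droplet_volume Droplet volume in microlitres.
#' @param dilution_to_droplet Scale factor from copies/g dry weight to
#'   copies per microlitre in the droplet reaction, or `"auto"` to dilute
#'   each measurement to a target droplet occupancy of 0.3 (standard ddPCR
#'   practice keeps occupancy mid-range; the factor used is recorded).
#' @param bio_sd_log10 Replicate-level lognormal noise (standard deviation in
#'   log10 units) applied to true concentrations before ddPCR observation.
#' @param community_template Data frame describing expected transconjugant
#'   community composition per sample group; see
#'   [default_community_template()].
#' @param dm_concentration Dirichlet precision of the community sampler;
#'   larger values give samples closer to the template.
#' @param seq_depth Reads per sorted-pool sample.
#' @param phase_boundaries Named list (per treatment) with elements `tp_end`
#'   and `mp_end`: day 0 is the initial phase (IP), days in `(0, tp_end]` the
#'   thermophilic phase (TP) and days in `(tp_end, mp_end]` (and beyond) the
#'   maturation phase (MP).
#' @param seed Integer seed controlling all randomness downstream.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [make_experiment()], [simulate_decay_trajectory()]
#' @examples
#' cfg <- synthetic_config(n_replicates = 2, seq_depth = 1000)
#' cfg$phase1_d_value
#' @export
synthetic_config <- function(treatments = c("NT", "CT"),
                             sampling_days = c(0, 1, 4, 7, 11, 15, 19, 27, 40),
                             n_replicates = 3,
                             donor_c0 = 3.30e6,
                             plasmid_c0 = 1.04e7,
                             total_16s_c0 = 7.264747e10,
                             phase1_d_value = 7,
                             phase2_d_value = 563,
                             breakpoint_day = 15,
                             rebound = list(NT = 0.03, CT = 0),
                             ddpcr_n_droplets = 20000,
                             ddpcr_droplet_volume = 0.00085,
                             dilution_to_droplet = "auto",
                             bio_sd_log10 = 0.1,
                             community_template = default_community_template(),
                             dm_concentration = 100,
                             seq_depth = 60000,
                             phase_boundaries = list(
                               NT = list(tp_end = 11, mp_end = 27),
                               CT = list(tp_end = 26, mp_end = 40)
                             ),
                             seed = 1L) {
  cfg <- structure(
    list(
      treatments = as.character(treatments),
      sampling_days = as.numeric(sampling_days),
      n_replicates = as.integer(n_replicates),
      donor_c0 = donor_c0,
      plasmid_c0 = plasmid_c0,
      total_16s_c0 = total_16s_c0,
      phase1_d_value = phase1_d_value,
      phase2_d_value = phase2_d_value,
      breakpoint_day = breakpoint_day,
      rebound = rebound,
      ddpcr_n_droplets = as.integer(ddpcr_n_droplets),
      ddpcr_droplet_volume = ddpcr_droplet_volume,
      dilution_to_droplet = dilution_to_droplet,
      bio_sd_log10 = bio_sd_log10,
      community_template = community_template,
      dm_concentration = dm_concentration,
      seq_depth = as.integer(seq_depth),
      phase_boundaries = phase_boundaries,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a synthetic experiment configuration
#'
#' Checks the structural invariants of a [synthetic_config()] object:
#' positive concentrations, a strictly increasing day grid starting at 0,
#' per-group template proportions summing to 1, and positive droplet and
#' read counts. Called by the constructor; exported so that configurations
#' deserialized from files can be re-checked.
#'
#' @param cfg A `synthetic_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) stop_values("not a synthetic_config object")
  if (length(cfg$treatments) < 1L) stop_values("at least one treatment required")
  d <- cfg$sampling_days
  if (length(d) < 2L || d[1] != 0 || any(diff(d) <= 0))
    stop_values("sampling_days must be strictly increasing and start at 0")
  for (f in c("donor_c0", "plasmid_c0", "total_16s_c0")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop_values("%s must be > 0", f)
  }
  if (cfg$phase1_d_value <= 0) stop_values("phase1_d_value must be > 0")
  if (cfg$phase2_d_value <= 0) stop_values("phase2_d_value must be > 0 (use Inf for none)")
  if (cfg$breakpoint_day <= 0) stop_values("breakpoint_day must be > 0")
  if (!all(cfg$treatments %in% names(cfg$rebound)))
    stop_values("rebound must name every treatment")
  if (cfg$n_replicates < 1L) stop_values("n_replicates must be >= 1")
  if (cfg$ddpcr_n_droplets < 1L) stop_values("ddpcr_n_droplets must be >= 1")
  if (cfg$ddpcr_droplet_volume <= 0) stop_values("ddpcr_droplet_volume must be > 0")
  if (cfg$seq_depth < 1L) stop_values("seq_depth must be >= 1")
  if (cfg$dm_concentration <= 0) stop_values("dm_concentration must be > 0")
  if (cfg$bio_sd_log10 < 0) stop_values("bio_sd_log10 must be >= 0")
  tpl <- cfg$community_template
  need <- c("group", "phylum", "genus", "otu_id", "prop")
  if (!all(need %in% names(tpl)))
    stop_values("community_template must have columns %s", paste(need, collapse = ", "))
  sums <- tapply(tpl$prop, tpl$group, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop_values("template proportions must sum to 1 per group (got %s)",
                paste(sprintf("%s=%.6f", names(sums), sums), collapse = ", "))
  if (any(tpl$prop < 0)) stop_values("template proportions must be >= 0")
  if (!all(cfg$treatments %in% names(cfg$phase_boundaries)))
    stop_values("phase_boundaries must name every treatment")
  for (tr in cfg$treatments) {
    pb <- cfg$phase_boundaries[[tr]]
    if (!(pb$tp_end > 0 && pb$mp_end > pb$tp_end))
      stop_values("phase boundaries for %s must satisfy 0 < tp_end < mp_end", tr)
  }
  invisible(cfg)
}

#' Assign composting phases to sampling days
#'
#' Day 0 is the initial phase (`IP`, raw material); days in `(0, tp_end]`
#' belong to the thermophilic phase (`TP`); later days to the maturation
#' phase (`MP`).
#'
#' @param day Numeric vector of days.
#' @param treatment Single treatment label.
#' @param cfg A `synthetic_config` (or any list with `phase_boundaries`).
#' @return Character vector of phase labels.
#' @export
assign_phase <- function(day, treatment, cfg) {
  pb <- cfg$phase_boundaries[[treatment]]
  if (is.null(pb)) stop_values("unknown treatment '%s'", treatment)
  ifelse(day == 0, "IP", ifelse(day <= pb$tp_end, "TP", "MP"))
}

# --- default transconjugant community template ------------------------------

# Pool of transconjugant OTUs spanning the eight phyla observed in sorted
# RP4 transconjugant pools. Genus labels follow the convention that OTUs
# unresolved at genus level are labelled by their nearest resolved rank with
# an "f__" prefix (e.g. "f__Bacillaceae").
transconjugant_otu_pool <- function() {
  g <- function(phylum, family, genus, n_otus) {
    data.frame(phylum = phylum, family = family, genus = genus,
               n_otus = n_otus, stringsAsFactors = FALSE)
  }
  pool <- rbind(
    # Firmicutes: spore-forming Bacillales dominate composting transconjugants
    g("Firmicutes", "Bacillaceae", "Bacillus", 6),
    g("Firmicutes", "Bacillaceae", "Oceanobacillus", 6),
    g("Firmicutes", "Bacillaceae", "f__Bacillaceae", 6),
    g("Firmicutes", "Bacillaceae", "Sinibacillus", 4),
    g("Firmicutes", "Staphylococcaceae", "Staphylococcus", 4),
    g("Firmicutes", "Planococcaceae", "Solibacillus", 4),
    g("Firmicutes", "Carnobacteriaceae", "Atopostipes", 4),
    g("Firmicutes", "Bacillaceae", "Amphibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Cerasibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Pseudogracilibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Anaerobacillus", 4),
    g("Firmicutes", "Lactobacillaceae", "Lactobacillus", 4),
    g("Firmicutes", "Bacillaceae", "Virgibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Lysinibacillus", 4),
    g("Firmicutes", "Paenibacillaceae", "Paenibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Ureibacillus", 4),
    g("Firmicutes", "Tissierellaceae", "Tepidimicrobium", 4),
    g("Firmicutes", "Caldicoprobacteraceae", "Caldicoprobacter", 4),
    g("Firmicutes", "Bacillaceae", "Gracilibacillus", 4),
    g("Firmicutes", "Bacillaceae", "Halobacillus", 4),
    g("Firmicutes", "Staphylococcaceae", "Salinicoccus", 4),
    g("Firmicutes", "Enterococcaceae", "Enterococcus", 4),
    g("Firmicutes", "Marinococcaceae", "f__Marinococcaceae", 4),
    g("Firmicutes", "Planifilaceae", "Planifilum", 4),
    # Proteobacteria: the phylum that rebounds during maturation
    g("Proteobacteria", "Halomonadaceae", "Halomonas", 4),
    g("Proteobacteria", "Fodinicurvataceae", "f__Fodinicurvataceae", 4),
    g("Proteobacteria", "Rhodobacteraceae", "Paracoccus", 4),
    g("Proteobacteria", "Pseudomonadaceae", "Pseudomonas", 4),
    g("Proteobacteria", "Enterobacteriaceae", "Escherichia-Shigella", 4),
    g("Proteobacteria", "Burkholderiaceae", "Burkholderia", 3),
    g("Proteobacteria", "Rhodobacteraceae", "Rubellimicrobium", 3),
    g("Proteobacteria", "Sphingomonadaceae", "Ellin6055", 3),
    g("Proteobacteria", "Moraxellaceae", "Acinetobacter", 3),
    g("Proteobacteria", "Devosiaceae", "Devosia", 3),
    g("Proteobacteria", "Sphingomonadaceae", "Sphingomonas", 3),
    g("Proteobacteria", "Rhizobiaceae", "f__Rhizobiaceae", 3),
    # Actinobacteria
    g("Actinobacteria", "Corynebacteriaceae", "Corynebacterium", 3),
    g("Actinobacteria", "Pseudonocardiaceae", "Saccharomonospora", 3),
    g("Actinobacteria", "Nocardiopsaceae", "Thermobifida", 3),
    g("Actinobacteria", "Streptomycetaceae", "Streptomyces", 3),
    g("Actinobacteria", "Mycobacteriaceae", "Mycobacterium", 3),
    g("Actinobacteria", "Bogoriellaceae", "Georgenia", 3),
    g("Actinobacteria", "Nocardiopsaceae", "Nocardiopsis", 3),
    g("Actinobacteria", "Thermomonosporaceae", "Actinomadura", 3),
    # minor phyla
    g("Halanaerobiaeota", "Halanaerobiaceae", "Halocella", 3),
    g("Halanaerobiaeota", "Halanaerobiaceae", "Halanaerobium", 3),
    g("Bacteroidota", "Flavobacteriaceae", "Flavobacterium", 3),
    g("Bacteroidota", "Sphingobacteriaceae", "Sphingobacterium", 3),
    g("Bacteroidota", "Dysgonomonadaceae", "Dysgonomonas", 3),
    g("Bacteroidota", "Dysgonomonadaceae", "Petrimonas", 3),
    g("Cyanobacteria", "Chloroplast", "f__Chloroplast", 3),
    g("Cyanobacteria", "Nostocaceae", "Cyanobacterium", 2),
    g("Myxococcota", "Haliangiaceae", "Haliangium", 2),
    g("Myxococcota", "Myxococcaceae", "Myxococcus", 2),
    g("Deinococcota", "Trueperaceae", "Truepera", 2),
    g("Deinococcota", "Deinococcaceae", "Deinococcus", 2)
  )
  otus <- pool[rep(seq_len(nrow(pool)), pool$n_otus), c("phylum", "family", "genus")]
  otus$otu_id <- sprintf("OTU%04d", seq_len(nrow(otus)))
  rownames(otus) <- NULL
  otus
}

# Phylum-level expected proportions per sample group. Firmicutes dominates
# throughout (75-90%); Proteobacteria rebounds at maturation; the
# Halanaerobiaeota lineage is eliminated by the end of composting.
.group_phylum_props <- list(
  "IP"    = c(Firmicutes = 0.800, Proteobacteria = 0.080, Actinobacteria = 0.060,
              Halanaerobiaeota = 0.030, Bacteroidota = 0.020, Cyanobacteria = 0.004,
              Myxococcota = 0.003, Deinococcota = 0.003),
  "NT-TP" = c(Firmicutes = 0.901, Proteobacteria = 0.043, Actinobacteria = 0.030,
              Halanaerobiaeota = 0.006, Bacteroidota = 0.012, Cyanobacteria = 0.003,
              Myxococcota = 0.003, Deinococcota = 0.002),
  "NT-MP" = c(Firmicutes = 0.753, Proteobacteria = 0.168, Actinobacteria = 0.040,
              Halanaerobiaeota = 0.000, Bacteroidota = 0.025, Cyanobacteria = 0.005,
              Myxococcota = 0.005, Deinococcota = 0.004),
  "CT-TP" = c(Firmicutes = 0.880, Proteobacteria = 0.082, Actinobacteria = 0.020,
              Halanaerobiaeota = 0.004, Bacteroidota = 0.008, Cyanobacteria = 0.002,
              Myxococcota = 0.002, Deinococcota = 0.002),
  "CT-MP" = c(Firmicutes = 0.755, Proteobacteria = 0.222, Actinobacteria = 0.010,
              Halanaerobiaeota = 0.000, Bacteroidota = 0.005, Cyanobacteria = 0.003,
              Myxococcota = 0.003, Deinococcota = 0.002)
)

# Dominant-genus anchors per group (overall expected proportions).
.group_genus_anchors <- list(
  "IP"    = c("Oceanobacillus" = 0.2741, "Bacillus" = 0.10, "Halocella" = 0.025),
  "NT-TP" = c("f__Bacillaceae" = 0.1966, "Bacillus" = 0.25, "Oceanobacillus" = 0.12),
  "NT-MP" = c("Bacillus" = 0.4841, "Oceanobacillus" = 0.0966, "Halomonas" = 0.0765,
              "f__Bacillaceae" = 0.0592, "f__Fodinicurvataceae" = 0.0341,
              "Sinibacillus" = 0.0307, "Staphylococcus" = 0.0307),
  "CT-TP" = c("Bacillus" = 0.4466, "Oceanobacillus" = 0.15, "f__Bacillaceae" = 0.10),
  "CT-MP" = c("Oceanobacillus" = 0.3023, "f__Bacillaceae" = 0.1363, "Bacillus" = 0.1265,
              "f__Fodinicurvataceae" = 0.0637, "Sinibacillus" = 0.0549,
              "f__Marinococcaceae" = 0.0372, "Paracoccus" = 0.0285)
)

# OTU richness (template support size) per group; encodes the observed
# ordering NT-TP > NT-MP ~ IP > CT-MP ~ CT-TP.
.group_support <- c("IP" = 96, "NT-TP" = 160, "NT-MP" = 106, "CT-TP" = 74, "CT-MP" = 80)

#' Default transconjugant community template
#'
#' Expected relative abundances of transconjugant OTUs for the five sample
#' groups of a two-treatment composting experiment: the shared raw material
#' (`IP`) and the end of the thermophilic (`TP`) and maturation (`MP`) phases
#' of the normal (`NT`) and continuous (`CT`) thermophilic treatments.
#'
#' The template places 75-90% of each community in Firmicutes across eight
#' phyla, rebounds Proteobacteria at maturation (4.3% to 16.8% in NT, 8.2% to
#' 22.2% in CT), anchors the dominant genera per group (e.g. Oceanobacillus
#' 27.41% in the raw material, Bacillus 44.66% in CT-TP and 48.41% in NT-MP)
#' and gives the continuous thermophilic treatment a markedly smaller OTU
#' support than the normal treatment, so that generated CT communities are
#' less rich and less diverse than NT communities. Non-anchor mass decays
#' geometrically down each phylum's OTU list.
#'
#' @return A data frame with columns `group`, `phylum`, `family`, `genus`,
#'   `otu_id` and `prop`; `prop` sums to 1 within each group.
#' @export
default_community_template <- function() {
  pool <- transconjugant_otu_pool()
  groups <- names(.group_phylum_props)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    pp <- .group_phylum_props[[grp]]
    anchors <- .group_genus_anchors[[grp]]
    support_n <- .group_support[[grp]]
    live <- names(pp)[pp > 0]
    pool_live <- pool[pool$phylum %in% live, ]
    # allocate support per phylum proportional to pool size, >= 1 each
    n_by_phy <- table(factor(pool_live$phylum, levels = live))
    k <- pmax(1L, round(support_n * as.numeric(n_by_phy) / nrow(pool_live)))
    names(k) <- live
    k <- pmin(k, as.numeric(n_by_phy))
    # adjust Firmicutes allocation to hit the exact support size
    k["Firmicutes"] <- k["Firmicutes"] + (support_n - sum(k))
    rows <- list()
    for (phy in live) {
      sub <- pool_live[pool_live$phylum == phy, ]
      anc <- anchors[names(anchors) %in% sub$genus]
      # supported OTUs: first OTU of each anchored genus, then pool order
      must <- vapply(names(anc), function(gn) which(sub$genus == gn)[1], integer(1))
      take <- unique(c(must, seq_len(nrow(sub))))[seq_len(k[[phy]])]
      sel <- sub[sort(take), ]
      prop <- numeric(nrow(sel))
      anchor_rows <- integer(0)
      for (gn in names(anc)) {
        idx <- which(sel$genus == gn)
        # spread an anchored genus' mass over its supported OTUs, front-loaded
        w <- 0.55 ^ seq_along(idx)
        prop[idx] <- prop[idx] + anc[[gn]] * w / sum(w)
        anchor_rows <- c(anchor_rows, idx)
      }
      rest <- setdiff(seq_len(nrow(sel)), anchor_rows)
      rem_mass <- pp[[phy]] - sum(anc)
      if (rem_mass < 0)
        stop_values("anchors exceed phylum mass for %s in %s", phy, grp)
      if (length(rest) > 0) {
        w <- 0.985 ^ seq_along(rest)
        prop[rest] <- rem_mass * w / sum(w)
      } else if (length(anchor_rows) > 0) {
        prop[anchor_rows[1]] <- prop[anchor_rows[1]] + rem_mass
      }
      sel$prop <- prop
      rows[[phy]] <- sel
    }
    gdf <- do.call(rbind, rows)
    gdf$group <- grp
    out[[gi]] <- gdf[, c("group", "phylum", "family", "genus", "otu_id", "prop")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
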