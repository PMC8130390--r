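# Seeded synthetic-data generators.
#
# Counts are negative binomial with log-normal library-size factors: the
# minimal model that reproduces the dropout / percent-expressing behavior the
# pipeline's count>0 logic depends on. Every generator returns a
# machine-readable truth record so each stage can be tested against planted
# ground truth without downloads.

# NB mean giving a target P(count > 0) at dispersion size theta
.nb_mu_for_pos <- function(p, theta) {
  p <- pmin(pmax(p, 0), 1 - 1e-12)
  theta * ((1 - p)^(-1 / theta) - 1)
}

# shared gene universe so atlas-derived candidates exist in the bulk panel
.synthetic_genes <- function(n_liver_specific = 24, n_broad_hep = 6) {
  list(liver = sprintf("LIV%03d", seq_len(n_liver_specific)),
       broad_hep = sprintf("HKH%02d", seq_len(n_broad_hep)))
}

#' Synthetic multi-cell-type atlas with planted type-specific genes
#'
#' Emulates a sorted single-cell compendium of many annotated cell types,
#' including progenitor-like types that the signature derivation excludes.
#' Every non-excluded type carries a planted set of specific genes expressed
#' (count > 0) in well over half of its cells and almost nowhere else; a
#' shared progenitor program, ubiquitously expressed genes and low-level
#' background genes provide the distractors the two-threshold filter must
#' reject. The hepatocyte set is split into genes that the default bulk
#' panel makes liver-specific and genes it makes broadly expressed, so the
#' bulk refinement stage has real work to do.
#'
#' @param seed RNG seed; same seed, same matrix.
#' @param n_cells_per_type cells simulated per type (default 60).
#' @param n_other_types number of non-excluded types besides the hepatocyte
#'   type (default 11, so the default `k = 12` tree cut matches the planted
#'   pattern groups).
#' @param n_excluded_types progenitor-like excluded types (default 8).
#' @param n_genes_per_type planted genes per non-hepatocyte type
#'   (default 15).
#' @param n_progenitor_genes,n_ubiquitous,n_background distractor gene
#'   counts.
#' @param in_type_mu NB mean of a planted gene in its own type (default 4,
#'   ~89 percent of cells positive at `nb_size = 2`).
#' @param bg_mu NB mean everywhere else (default 0.01; 0 gives exactly zero
#'   off-type counts).
#' @param nb_size NB dispersion parameter (default 2).
#' @param lib_sdlog sdlog of the log-normal library-size factor
#'   (default 0.25).
#' @param planted optional named list type -> gene IDs overriding the planted
#'   sets; sets must be disjoint.
#' @return list with `matrix` (counts [expression_matrix]), `type_labels`
#'   (named by unit), and `truth` (planted sets, excluded types, hepatocyte
#'   and liver-specific gene sets).
#' @export
generate_atlas <- function(seed = 1, n_cells_per_type = 60,
                           n_other_types = 11, n_excluded_types = 8,
                           n_genes_per_type = 15, n_progenitor_genes = 40,
                           n_ubiquitous = 150, n_background = 215,
                           in_type_mu = 4, bg_mu = 0.01, nb_size = 2,
                           lib_sdlog = 0.25, planted = NULL) {
  if (n_other_types + 1 + n_excluded_types < 3)
    stop("need at least 3 cell types")
  set.seed(seed)
  excluded_types <- sprintf("progenitor_%02d", seq_len(n_excluded_types))
  other_types <- sprintf("somatic_%02d", seq_len(n_other_types))
  types <- c("hepatocyte", other_types, excluded_types)

  sg <- .synthetic_genes()
  hep_genes <- c(sg$liver, sg$broad_hep)
  if (is.null(planted)) {
    planted <- c(list(hepatocyte = hep_genes),
                 setNames(lapply(seq_along(other_types), function(i)
                   sprintf("TS%02dG%03d", i, seq_len(n_genes_per_type))),
                   other_types))
  } else {
    all_p <- unlist(planted)
    if (anyDuplicated(all_p))
      stop("planted gene sets overlap: ",
           paste(head(unique(all_p[duplicated(all_p)]), 3), collapse = ", "))
  }
  prog_genes <- sprintf("PRG%03d", seq_len(n_progenitor_genes))
  ubq_genes <- sprintf("UBQ%03d", seq_len(n_ubiquitous))
  bg_genes <- sprintf("BGA%03d", seq_len(n_background))
  genes <- c(unlist(planted, use.names = FALSE), prog_genes, ubq_genes,
             bg_genes)

  n_cells <- n_cells_per_type * length(types)
  type_of <- rep(types, each = n_cells_per_type)
  cells <- sprintf("AT%05d", seq_len(n_cells))

  # per-gene x per-type NB mean
  mu <- matrix(bg_mu, length(genes), length(types),
               dimnames = list(genes, types))
  for (t in names(planted)) mu[planted[[t]], t] <- in_type_mu
  mu[prog_genes, excluded_types] <- in_type_mu
  mu[ubq_genes, ] <- 1.5        # expressed everywhere, incl. excluded types
  mu[bg_genes, ] <- 0.3         # low-level noise, fails the high filter

  lib <- rlnorm(n_cells, 0, lib_sdlog)
  cell_mu <- mu[, type_of, drop = FALSE] *
    matrix(lib, length(genes), n_cells, byrow = TRUE)
  counts <- matrix(rnbinom(length(cell_mu), size = nb_size, mu = cell_mu),
                   length(genes), n_cells, dimnames = list(genes, cells))
  m <- expression_matrix(counts, genes, cells, modality = "counts")
  list(matrix = m,
       type_labels = setNames(type_of, cells),
       truth = list(planted = planted,
                    excluded_types = excluded_types,
                    hepatocyte_genes = hep_genes,
                    liver_genes = sg$liver,
                    broad_hep_genes = sg$broad_hep))
}

#' Synthetic bulk tissue panel with planted tissue-specific genes
#'
#' Emulates a multi-tissue bulk expression panel: log-normal TPM-like values
#' with the planted liver-specific genes elevated only in liver samples, and
#' the broad hepatocyte genes elevated in every tissue (liver-expressed but
#' not liver-specific). Used to refine an atlas-derived candidate set.
#'
#' @param seed RNG seed.
#' @param tissues tissue names; must include `target_tissue` of downstream
#'   calls (default 12 tissues incl. `"Liver"`).
#' @param n_samples_per_tissue samples per tissue (default 8).
#' @param extra_genes additional background genes included in the panel.
#' @param effect log2 elevation of planted genes in their tissue(s)
#'   (default 4).
#' @param base_mean,base_sd per-gene baseline log2 expression distribution.
#' @param noise_sd per-sample log2 noise (default 0.5; 0 gives noiseless
#'   recovery).
#' @return list with `matrix` (modality `"tpm"`), `tissue_labels` (named by
#'   sample), and `truth` (`liver_genes`, `broad_hep_genes`).
#' @export
generate_bulk_panel <- function(seed = 1,
                                tissues = c("Liver", "Brain", "Heart",
                                            "Lung", "Kidney", "Muscle",
                                            "Pancreas", "Spleen", "Stomach",
                                            "Skin", "Testis", "Blood"),
                                n_samples_per_tissue = 8,
                                extra_genes = 300, effect = 4,
                                base_mean = 3, base_sd = 1, noise_sd = 0.5) {
  if (length(tissues) < 2) stop("need >= 2 tissues")
  set.seed(seed)
  sg <- .synthetic_genes()
  genes <- c(sg$liver, sg$broad_hep,
             sprintf("BGB%03d", seq_len(extra_genes)))
  tissue_of <- rep(tissues, each = n_samples_per_tissue)
  samples <- sprintf("%s_S%02d", tissue_of,
                     sequence(rep(n_samples_per_tissue, length(tissues))))
  base <- rnorm(length(genes), base_mean, base_sd)
  log2x <- matrix(base, length(genes), length(samples),
                  dimnames = list(genes, samples))
  log2x[sg$liver, tissue_of == "Liver"] <-
    log2x[sg$liver, tissue_of == "Liver"] + effect
  log2x[sg$broad_hep, ] <- log2x[sg$broad_hep, ] + effect
  # shared per-sample shift (depth/batch-like): after Z-scoring it gives
  # broadly expressed genes a coherent common profile, as in real panels,
  # instead of leaving them as mutually independent unit-variance noise rows
  sample_shift <- rnorm(length(samples), 0, noise_sd)
  log2x <- log2x + rep(sample_shift, each = length(genes)) +
    matrix(rnorm(length(log2x), 0, noise_sd), nrow(log2x))
  m <- expression_matrix(2^log2x, genes, samples, modality = "tpm")
  list(matrix = m,
       tissue_labels = setNames(tissue_of, samples),
       truth = list(liver_genes = sg$liver,
                    broad_hep_genes = sg$broad_hep))
}

#' Synthetic tumor / para-carcinoma single-cell dataset
#'
#' Emulates a paired tumor and para-carcinoma single-cell experiment with a
#' bimodal hepatocyte-index structure: hepatocytes are generated so that
#' their mean-of-Z index over the planted hepatocyte signature is
#' approximately normal (`hep_mu`, `hep_sigma`) while non-hepatocytes follow
#' a shifted exponential (`nonhep_rate`). The per-gene Z-transform couples
#' cells: any index of Z-scores has mean exactly 0 across cells and a
#' population scale equal to the signal fraction of the per-gene variance,
#' so linear rescaling of planted effect sizes cannot move the realized
#' index scale. The realized index is `rho * standardized(target)` where
#' `rho` (<= 1) is the per-gene signal-to-noise attenuation; the defaults
#' therefore use highly expressed, mildly dispersed signature genes
#' (`hep_base_mean`, `sig_nb_size`) so that `rho` matches the target
#' mixture's standard deviation and the realized component parameters land
#' close to the configured targets.
#' A rare proliferative subset carries a strongly elevated second signature;
#' macrophages express the canonical markers with tissue-dependent SLC40A1
#' and Kupffer-gene (CD5L/CETP/MARCO/CFP) positivity; HAMP is planted as
#' para-hepatocyte-specific.
#'
#' @param seed RNG seed.
#' @param n_cells total cells (default 6000, split over patients and
#'   tumor/para tissues).
#' @param n_patients patients, each contributing a tumor and a para sample
#'   (default 3).
#' @param hepatocyte_frac,macrophage_frac expected class fractions (the
#'   remainder are "other"; defaults 0.45 / 0.15).
#' @param prolif_frac fraction of hepatocytes that are proliferative
#'   (default 0.01).
#' @param hep_mu,hep_sigma target normal location/scale of the hepatocyte
#'   index (defaults 1.0 / 0.25 on the Z-index scale).
#' @param nonhep_rate target exponential rate of the non-hepatocyte index
#'   (default 5; the exponential origin is placed so the overall index mean
#'   is zero, as the Z-transform forces).
#' @param n_hep_genes,n_s1_genes planted signature sizes (defaults 142 / 87,
#'   gene IDs `HSIG###` / `S1G###`).
#' @param marker_pos per-marker positivity of macrophage markers in
#'   macrophages (default 0.85).
#' @param slc40a1_pos named vector, SLC40A1 positivity of macrophages per
#'   tissue (default `c(para = 0.7, tumor = 0.4)`).
#' @param kupffer_pos named vector, positivity of each of CD5L/CETP/MARCO/CFP
#'   in macrophages per tissue (default `c(para = 0.7, tumor = 0.2)`).
#' @param hamp_pos named vector, HAMP positivity of hepatocytes per tissue
#'   (default `c(para = 0.8, tumor = 0.02)`).
#' @param n_background background genes carrying the library depth
#'   (default 600).
#' @param hep_base_mean mean baseline count of a hepatocyte-signature gene
#'   per unit of latent activity (default 15; hepatocyte-signature genes are
#'   among the most highly expressed in liver data).
#' @param sig_nb_size NB dispersion of the hepatocyte-signature genes
#'   (default 30, i.e. mild biological overdispersion beyond the planted
#'   program).
#' @param s1_effect additive latent activity of the proliferation program in
#'   proliferative cells (default 12, a strong planted burst).
#' @param nb_size NB dispersion of all other genes (default 2).
#' @param lib_sdlog sdlog of the library-size factor (default 0.25).
#' @return list with `matrix` (counts, with tumor/para `unit_meta`),
#'   `truth` (data.frame: unit_id, cell_type, is_proliferative, tissue,
#'   sample, latent hep-index target), `hep_signature` and `s1_signature`
#'   ([gene_signature]s of the planted sets).
#' @export
generate_tumor_para <- function(seed = 1, n_cells = 6000, n_patients = 3,
                                hepatocyte_frac = 0.45,
                                macrophage_frac = 0.15,
                                prolif_frac = 0.01,
                                hep_mu = 1.0, hep_sigma = 0.25,
                                nonhep_rate = 5,
                                n_hep_genes = 142, n_s1_genes = 87,
                                marker_pos = 0.85,
                                slc40a1_pos = c(para = 0.7, tumor = 0.4),
                                kupffer_pos = c(para = 0.7, tumor = 0.2),
                                hamp_pos = c(para = 0.8, tumor = 0.02),
                                n_background = 600, hep_base_mean = 15,
                                sig_nb_size = 30, s1_effect = 4,
                                nb_size = 2, lib_sdlog = 0.25) {
  if (hepatocyte_frac + macrophage_frac >= 1)
    stop("class fractions must leave room for 'other' cells")
  if (prolif_frac == 0)
    warning("prolif_frac = 0: no proliferative cells will be planted")

  hep_genes <- sprintf("HSIG%03d", seq_len(n_hep_genes))
  s1_genes <- sprintf("S1G%03d", seq_len(n_s1_genes))
  markers <- .MACROPHAGE_MARKERS
  kupffer <- c("CD5L", "CETP", "MARCO", "CFP")
  bg_genes <- sprintf("BGC%03d", seq_len(n_background))
  genes <- c(hep_genes, s1_genes, markers, "SLC40A1", "HAMP", kupffer,
             bg_genes)
  n_genes <- length(genes)

  # --- cell frame (fixed across calibration passes) -----------------------
  set.seed(seed)
  patients <- sprintf("HS%02d", seq_len(n_patients))
  patient_of <- sample(rep_len(patients, n_cells))
  tissue_of <- sample(rep_len(c("tumor", "para"), n_cells))
  sample_of <- paste0(patient_of, ifelse(tissue_of == "tumor", "T", "N"))
  cell_type <- sample(c("hepatocyte", "macrophage", "other"), n_cells,
                      replace = TRUE,
                      prob = c(hepatocyte_frac, macrophage_frac,
                               1 - hepatocyte_frac - macrophage_frac))
  is_hep <- cell_type == "hepatocyte"
  is_mac <- cell_type == "macrophage"
  is_prolif <- is_hep & runif(n_cells) < prolif_frac
  cells <- sprintf("TP%05d", seq_len(n_cells))

  # latent hepatocyte-index target: normal mode for hepatocytes, shifted
  # exponential for the rest; origin placed so the population mean is ~0
  # (the Z-transform forces a zero-mean index)
  w <- mean(is_hep)
  e_shift <- -(w * hep_mu + (1 - w) / nonhep_rate) / (1 - w)
  target <- numeric(n_cells)
  target[is_hep] <- rnorm(sum(is_hep), hep_mu, hep_sigma)
  target[!is_hep] <- e_shift + rexp(sum(!is_hep), nonhep_rate)

  lib <- rlnorm(n_cells, 0, lib_sdlog)
  hep_base <- exp(rnorm(n_hep_genes, log(hep_base_mean), 0.3))
  s1_base <- exp(rnorm(n_s1_genes, log(3), 0.3))
  bg_mu_gene <- exp(rnorm(n_background, log(6), 0.8)) # depth ballast

  pos_mu <- function(p) .nb_mu_for_pos(p, nb_size)

  # positive affine image of the latent target; the Z-transform strips the
  # affine part again, so only the shape reaches the realized index
  act <- target - min(target) + 0.02 * diff(range(target))
  s1_act <- 0.03 + s1_effect * as.numeric(is_prolif)

  mu <- matrix(0.005, n_genes, n_cells, dimnames = list(genes, cells))
  mu[hep_genes, ] <- hep_base %o% act
  mu[s1_genes, ] <- s1_base %o% s1_act
  # the proliferation burst displaces background transcription at fixed
  # library size, so it does not dilute the hepatocyte-gene proportions
  # (RP10K measures proportions; without this, planted proliferative cells
  # would read as artificially de-differentiated)
  bg_scale <- rep(1, n_cells)
  bg_total <- sum(bg_mu_gene)
  s1_extra <- s1_effect * sum(s1_base)
  bg_scale[is_prolif] <- max(0.1, (bg_total - s1_extra) / bg_total)
  for (g in markers) mu[g, is_mac] <- pos_mu(marker_pos)
  mu["SLC40A1", is_mac] <- pos_mu(slc40a1_pos[tissue_of[is_mac]])
  for (g in kupffer) mu[g, is_mac] <- pos_mu(kupffer_pos[tissue_of[is_mac]])
  mu["HAMP", is_hep] <- pos_mu(hamp_pos[tissue_of[is_hep]])
  mu[bg_genes, ] <- bg_mu_gene %o% bg_scale
  mu <- mu * matrix(lib, n_genes, n_cells, byrow = TRUE)
  size <- ifelse(genes %in% hep_genes, sig_nb_size, nb_size)
  counts <- matrix(rnbinom(length(mu), size = rep(size, n_cells), mu = mu),
                   n_genes, n_cells, dimnames = list(genes, cells))

  unit_meta <- data.frame(unit_id = cells, tissue = tissue_of,
                          sample = sample_of, stringsAsFactors = FALSE)
  m <- expression_matrix(counts, genes, cells, modality = "counts",
                         unit_meta = unit_meta)
  truth <- data.frame(unit_id = cells, cell_type = cell_type,
                      is_proliferative = is_prolif, tissue = tissue_of,
                      sample = sample_of, hep_target = target,
                      stringsAsFactors = FALSE)
  list(matrix = m, truth = truth,
       hep_signature = gene_signature("Hep", hep_genes,
                                      provenance = list(source = "synthetic",
                                                        seed = seed)),
       s1_signature = gene_signature("S1", s1_genes,
                                     provenance = list(source = "synthetic",
                                                       seed = seed)))
}

#' Synthetic developmental bulk time series with two opposing programs
#'
#' Emulates bulk expression of a developing tissue: one gene program rises
#' monotonically across timepoints (differentiation), a second falls
#' (proliferation), plus background genes. Program-level noise is sized so
#' the Pearson correlation between the two signature indexes has the
#' configured expectation (`target_cor`, default -0.9); with
#' `target_cor = -1` and `gene_noise_sd = 0` the recovery is exact.
#'
#' @param seed RNG seed.
#' @param n_timepoints number of timepoints, `>= 5` (default 16).
#' @param n_up_genes,n_down_genes genes in the rising / falling program
#'   (defaults 100 / 80).
#' @param n_background background genes (default 200).
#' @param target_cor target expected Pearson correlation between the two
#'   indexes (default -0.9, must be in \[-1, 0)).
#' @param gene_noise_sd per-gene log2 noise sd (default 0.05).
#' @return list with `matrix` (modality `"fpkm"`, log2-scale values, one
#'   sample per timepoint),
#'   `timepoints` (ordered labels), `up_signature`, `down_signature`
#'   ([gene_signature]s) and `truth` (latent program values and
#'   `target_cor`).
#' @export
generate_dev_timeseries <- function(seed = 1, n_timepoints = 16,
                                    n_up_genes = 100, n_down_genes = 80,
                                    n_background = 200, target_cor = -0.9,
                                    gene_noise_sd = 0.05) {
  if (n_timepoints < 5) stop("need >= 5 timepoints")
  if (!(target_cor >= -1 && target_cor < 0))
    stop("target_cor must lie in [-1, 0)")
  set.seed(seed)
  tp <- sprintf("T%02d", seq_len(n_timepoints))
  trend <- seq(-1, 1, length.out = n_timepoints)
  rho <- abs(target_cor)
  prog_sd <- sd(trend) * sqrt((1 - rho) / rho)
  up <- trend + rnorm(n_timepoints, 0, prog_sd)
  dn <- -trend + rnorm(n_timepoints, 0, prog_sd)

  up_genes <- sprintf("DVU%03d", seq_len(n_up_genes))
  dn_genes <- sprintf("DVD%03d", seq_len(n_down_genes))
  bg_genes <- sprintf("BGD%03d", seq_len(n_background))
  genes <- c(up_genes, dn_genes, bg_genes)
  base <- rnorm(length(genes), 4, 1)
  slope <- c(runif(n_up_genes, 0.8, 1.2), runif(n_down_genes, 0.8, 1.2),
             rep(0, n_background))
  prog <- rbind(matrix(up, n_up_genes, n_timepoints, byrow = TRUE),
                matrix(dn, n_down_genes, n_timepoints, byrow = TRUE),
                matrix(0, n_background, n_timepoints))
  log2x <- base + slope * prog +
    matrix(rnorm(length(genes) * n_timepoints, 0, gene_noise_sd),
           length(genes), n_timepoints)
  dimnames(log2x) <- list(genes, tp)
  # emitted on the log2 scale (log2 FPKM-like): the per-gene Z-transform is
  # then linear in the latent programs, so the index correlation hits the
  # configured target in expectation (and -1 exactly in the noiseless limit)
  m <- expression_matrix(log2x, genes, tp, modality = "fpkm")
  list(matrix = m, timepoints = tp,
       up_signature = gene_signature("Hep_dev", up_genes,
                                     provenance = list(source = "synthetic")),
       down_signature = gene_signature("S1_dev", dn_genes,
                                       provenance = list(source = "synthetic")),
       truth = list(up_program = up, down_program = dn,
                    target_cor = target_cor))
}
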