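#' Synthetic compendium configuration
#'
#' Parameters of the synthetic multi-study expression compendium. The
#' defaults emulate the design of a multi-study tumor/cell-line/normal
#' compendium on a single platform: eight tissues, cell-line counts of
#' 6-9 per tissue, scaled-down tumor (10-20) and normal (7-20) group
#' sizes, about 17% of genes in the membranome, tissue signatures
#' concentrated in the membranome (`rho`), tissue-specific planted tumor
#' deregulation with asymmetric retention in the cognate cell lines
#' (`r_up < r_down`: up-regulations are mostly lost in vitro while
#' down-regulations persist), a tumor-only immune-infiltrate block (TIL)
#' absent from the clonal cell lines, per-study additive batch offsets,
#' and Gaussian residual noise on the log2 scale.
#'
#' @param n_genes total number of genes.
#' @param membranome_fraction fraction of genes in the membranome pool.
#' @param tissues character vector of tissue names.
#' @param n_tumor,n_cellline,n_normal per-tissue sample counts (recycled
#'   or named by tissue).
#' @param n_signature signature genes per tissue (tissue identity,
#'   expressed in all classes of that tissue).
#' @param rho fraction of each tissue signature drawn from the membranome.
#' @param beta signature effect, log2 units.
#' @param n_up,n_down planted tumor-deregulated membranome genes per
#'   tissue.
#' @param delta_up,delta_down deregulation effects, log2 units.
#' @param r_up,r_down probability that a tumor up-/down-regulation is
#'   retained in the cognate cell line.
#' @param til_block,til_effect size and effect of the tumor-only immune
#'   admixture block.
#' @param sigma_batch standard deviation of per-study per-gene offsets.
#' @param sigma residual noise standard deviation (log2 units).
#' @param baseline_mean,baseline_sd distribution of baseline gene means.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2500L,
                         membranome_fraction = 0.17,
                         tissues = c("brain", "breast", "colon", "kidney",
                                     "leukemia", "lung", "melanoma", "ovary"),
                         n_tumor = c(15L, 14L, 15L, 11L, 20L, 20L, 10L, 14L),
                         n_cellline = c(6L, 6L, 7L, 8L, 6L, 9L, 8L, 6L),
                         n_normal = c(9L, 8L, 9L, 14L, 8L, 20L, 8L, 7L),
                         n_signature = 30L, rho = 0.8, beta = 2,
                         n_up = 40L, n_down = 40L,
                         delta_up = 1.5, delta_down = 1.5,
                         r_up = 0.5, r_down = 0.8,
                         til_block = 30L, til_effect = 1,
                         sigma_batch = 0.1, sigma = 0.4,
                         baseline_mean = 7, baseline_sd = 1.5,
                         seed = 42L) {
  tissues <- as.character(tissues)
  expand <- function(v) {
    if (!is.null(names(v))) return(as.integer(v[tissues]))
    as.integer(rep_len(v, length(tissues)))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              membranome_fraction = membranome_fraction,
              tissues = tissues,
              n_tumor = stats::setNames(expand(n_tumor), tissues),
              n_cellline = stats::setNames(expand(n_cellline), tissues),
              n_normal = stats::setNames(expand(n_normal), tissues),
              n_signature = as.integer(n_signature), rho = rho, beta = beta,
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              delta_up = delta_up, delta_down = delta_down,
              r_up = r_up, r_down = r_down,
              til_block = as.integer(til_block), til_effect = til_effect,
              sigma_batch = sigma_batch, sigma = sigma,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  probs <- c(membranome_fraction = membranome_fraction, rho = rho,
             r_up = r_up, r_down = r_down)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  n_mem <- round(cfg$n_genes * membranome_fraction)
  need_mem <- length(tissues) * (cfg$n_up + cfg$n_down)
  if (cfg$n_up + cfg$n_down + cfg$n_signature > n_mem)
    stop("per-tissue planted + signature genes exceed the membranome pool")
  if (cfg$n_signature * length(tissues) + cfg$til_block > cfg$n_genes)
    stop("signature genes exceed the gene universe")
  if (any(c(cfg$n_tumor, cfg$n_cellline, cfg$n_normal) < 0))
    stop("negative sample counts")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic expression compendium with known truth
#'
#' Sample value = baseline gene mean + tissue signature effect (signature
#' genes, samples of that tissue, all classes) + planted deregulation
#' (tumors of the cognate tissue; cell lines only where the effect is
#' retained) + TIL admixture effect (tumor samples only) + per-study batch
#' offset + Gaussian noise. Values are on the log2 scale; `scale = "linear"`
#' exports `2^x` for exercising the preprocessing chain. Deterministic
#' given the seed.
#'
#' @param config a [synth_config()].
#' @param scale `"log2"` (default) or `"linear"`.
#' @param seed optional override of `config$seed`.
#' @return list with `dataset` (an `expression_dataset`), `truth` (long
#'   data.frame: gene_id, tissue, signature, planted_up, planted_down,
#'   retained_in_cellline, til_block, membranome) and the `config`.
#' @export
generate_dataset <- function(config = synth_config(), scale = c("log2", "linear"),
                             seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  scale <- match.arg(scale)
  restore <- local_rng(seed)
  on.exit(restore())
  ng <- config$n_genes
  genes <- sprintf("g%05d", seq_len(ng))
  n_mem <- round(ng * config$membranome_fraction)
  membranome <- sort(sample(genes, n_mem))
  non_mem <- setdiff(genes, membranome)

  # disjoint tissue signatures, membranome-concentrated
  avail_mem <- setdiff(membranome, character())
  avail_non <- non_mem
  n_sig_mem <- round(config$rho * config$n_signature)
  n_sig_non <- config$n_signature - n_sig_mem
  signature <- list()
  for (t in config$tissues) {
    sm <- if (n_sig_mem > 0) sample(avail_mem, n_sig_mem) else character()
    sn <- if (n_sig_non > 0) sample(avail_non, n_sig_non) else character()
    avail_mem <- setdiff(avail_mem, sm)
    avail_non <- setdiff(avail_non, sn)
    signature[[t]] <- c(sm, sn)
  }
  # tumor-only immune admixture block (shared across tissues)
  til <- if (config$til_block > 0) sample(avail_non, config$til_block) else character()

  # tissue-specific planted deregulation within the membranome,
  # independent across tissues, avoiding that tissue's own signature
  planted_up <- planted_down <- retained <- list()
  for (t in config$tissues) {
    pool <- setdiff(membranome, signature[[t]])
    pick <- sample(pool, config$n_up + config$n_down)
    planted_up[[t]] <- pick[seq_len(config$n_up)]
    planted_down[[t]] <- pick[config$n_up + seq_len(config$n_down)]
    keep_up <- planted_up[[t]][stats::runif(config$n_up) < config$r_up]
    keep_down <- planted_down[[t]][stats::runif(config$n_down) < config$r_down]
    retained[[t]] <- c(keep_up, keep_down)
  }

  # manifest: cell lines share one study; tumors and normals one study per tissue
  man_rows <- list()
  for (t in config$tissues) {
    add <- function(cls, nn, study) {
      if (nn == 0L) return(NULL)
      data.frame(sample_id = sprintf("%s_%s_%02d", t, cls, seq_len(nn)),
                 tissue = t, sample_class = cls, study_id = study,
                 replicate_group = NA_character_, stringsAsFactors = FALSE)
    }
    man_rows[[t]] <- rbind(add("tumor", config$n_tumor[t], paste0("study_tumor_", t)),
                           add("cell_line", config$n_cellline[t], "study_celllines"),
                           add("normal", config$n_normal[t], paste0("study_normal_", t)))
  }
  man <- do.call(rbind, c(man_rows, make.row.names = FALSE))
  ns <- nrow(man)

  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  m <- matrix(baseline, ng, ns, dimnames = list(genes, man$sample_id))
  # per-study per-gene batch offsets
  for (st in unique(man$study_id)) {
    off <- stats::rnorm(ng, 0, config$sigma_batch)
    cols <- man$study_id == st
    m[, cols] <- m[, cols] + off
  }
  for (t in config$tissues) {
    in_t <- man$tissue == t
    m[signature[[t]], in_t] <- m[signature[[t]], in_t] + config$beta
    tum <- in_t & man$sample_class == "tumor"
    cl <- in_t & man$sample_class == "cell_line"
    m[planted_up[[t]], tum] <- m[planted_up[[t]], tum] + config$delta_up
    m[planted_down[[t]], tum] <- m[planted_down[[t]], tum] - config$delta_down
    ru <- intersect(planted_up[[t]], retained[[t]])
    rd <- intersect(planted_down[[t]], retained[[t]])
    m[ru, cl] <- m[ru, cl] + config$delta_up
    m[rd, cl] <- m[rd, cl] - config$delta_down
  }
  tum_all <- man$sample_class == "tumor"
  if (length(til) > 0) m[til, tum_all] <- m[til, tum_all] + config$til_effect
  m <- m + matrix(stats::rnorm(ng * ns, 0, config$sigma), ng, ns)

  truth <- do.call(rbind, lapply(config$tissues, function(t) {
    data.frame(gene_id = genes, tissue = t,
               signature = genes %in% signature[[t]],
               planted_up = genes %in% planted_up[[t]],
               planted_down = genes %in% planted_down[[t]],
               retained_in_cellline = genes %in% retained[[t]],
               til_block = genes %in% til,
               membranome = genes %in% membranome,
               stringsAsFactors = FALSE)
  }))
  if (scale == "linear") m <- 2^m
  ds <- expression_dataset(m, man, scale_state = if (scale == "linear") "linear" else "log2")
  list(dataset = ds, truth = truth, config = config)
}

#' Membranome gene IDs from a truth table
#'
#' @param truth the long truth data.frame from [generate_dataset()].
#' @return character vector of membranome gene IDs.
#' @export
truth_membranome <- function(truth) {
  unique(truth$gene_id[truth$membranome])
}

#' The reference compendium design
#'
#' Per-tissue sample counts of the real multi-study compendium the
#' synthetic generator emulates: 56 NCI60-derived cell lines, 294 primary
#' tumors and 59 normal samples (409 arrays in total) across eight
#' tissues, with normal samples available for five of them.
#'
#' @return data.frame with columns tissue, cell_lines, normals, tumors.
#' @export
reference_design <- function() {
  data.frame(
    tissue = c("brain", "breast", "colon", "kidney", "leukemia", "lung",
               "melanoma", "ovary"),
    cell_lines = c(6L, 6L, 7L, 8L, 6L, 9L, 8L, 6L),
    normals = c(9L, 0L, 9L, 14L, 0L, 20L, 0L, 7L),
    tumors = c(21L, 19L, 21L, 11L, 72L, 127L, 9L, 14L),
    stringsAsFactors = FALSE)
}

#' Expand a per-tissue design into a sample-level manifest
#'
#' @param design data.frame as returned by [reference_design()].
#' @return manifest data.frame (sample_id, tissue, sample_class, study_id).
#' @export
design_manifest <- function(design = reference_design()) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    t <- design$tissue[i]
    mk <- function(cls, nn, study) {
      if (nn == 0L) return(NULL)
      data.frame(sample_id = sprintf("%s_%s_%03d", t, cls, seq_len(nn)),
                 tissue = t, sample_class = cls, study_id = study,
                 stringsAsFactors = FALSE)
    }
    rbind(mk("cell_line", design$cell_lines[i], "study_celllines"),
          mk("normal", design$normals[i], paste0("study_normal_", t)),
          mk("tumor", design$tumors[i], paste0("study_tumor_", t)))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Totals of a sample manifest
#'
#' @param manifest a manifest data.frame with `sample_class`.
#' @return named list: n_samples, n_tumors, n_celllines, n_normals.
#' @export
manifest_totals <- function(manifest) {
  cls <- manifest$sample_class
  list(n_samples = length(cls),
       n_tumors = sum(cls == "tumor"),
       n_celllines = sum(cls == "cell_line"),
       n_normals = sum(cls == "normal"))
}
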