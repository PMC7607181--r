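# Relative expression from qPCR crossing points (2^ddCp) and western-blot
# densitometry normalization.

#' Delta-Cp relative to the reference gene
#'
#' dCp = Cp(reference) - Cp(gene of interest): a HIGHER dCp means higher
#' expression (the gene crosses threshold fewer cycles after the abundant
#' reference).
#'
#' @param cp_gene,cp_reference numeric crossing points (finite, > 0).
#' @return numeric dCp.
#' @export
delta_cp <- function(cp_gene, cp_reference) {
  if (anyNA(cp_reference))
    abort("missing reference Cp", "ihcmet_param_error")
  if (!all(is.finite(cp_gene) & cp_gene > 0) ||
      !all(is.finite(cp_reference) & cp_reference > 0))
    abort("Cp values must be finite and > 0", "ihcmet_param_error")
  cp_reference - cp_gene
}

#' Fold change as 2^ddCp
#'
#' ddCp = dCp(treated) - mean dCp(control); multiple control replicates
#' are combined by the arithmetic mean of dCp (equivalently the geometric
#' mean of 2^dCp). Returns 2^ddCp per treated sample.
#'
#' @param dcp_treated numeric dCp values of the treated group.
#' @param dcp_control numeric dCp values of the control group (non-empty).
#' @return numeric fold changes (> 0), one per treated sample.
#' @export
fold_change <- function(dcp_treated, dcp_control) {
  if (!length(dcp_control))
    abort("empty control group", "ihcmet_param_error")
  2^(dcp_treated - mean(dcp_control))
}

#' Per-gene fold changes from a long qPCR table
#'
#' @param records data.frame with columns `sample_id`, `condition`,
#'   `gene`, `cp`, `cp_reference`.
#' @param control_condition label of the control group.
#' @return data.frame per sample and gene with `dcp` and `fold`; attribute
#'   `group_geometric_means` holds per-condition/gene geometric-mean folds.
#' @export
qpcr_fold_changes <- function(records, control_condition) {
  need <- c("sample_id", "condition", "gene", "cp", "cp_reference")
  if (!all(need %in% names(records)))
    abort(paste("records must contain", paste(need, collapse = ", ")),
          "ihcmet_format_error")
  if (!control_condition %in% records$condition)
    abort("control condition not present", "ihcmet_param_error")
  records$dcp <- delta_cp(records$cp, records$cp_reference)
  out <- do.call(rbind, lapply(split(records, records$gene), function(g) {
    ctrl <- g$dcp[g$condition == control_condition]
    g$fold <- fold_change(g$dcp, ctrl)
    g
  }))
  rownames(out) <- NULL
  gm <- aggregate(fold ~ condition + gene, data = out,
                  FUN = function(f) exp(mean(log(f))))
  names(gm)[3] <- "geometric_mean_fold"
  attr(out, "group_geometric_means") <- gm
  out
}

#' Normalize densitometry to loading control and reference sample
#'
#' fold = (band / loading) / (band_ref / loading_ref); the reference
#' sample maps to exactly 1. Invariant to rescaling all densities on a
#' blot by a common factor.
#'
#' @param band numeric integrated band densities (> 0).
#' @param loading numeric loading-control densities (> 0).
#' @param reference index (or logical mask) of the single reference sample.
#' @return numeric fold per sample.
#' @export
normalize_density <- function(band, loading, reference = 1L) {
  if (any(band <= 0) || any(loading <= 0))
    abort("densities must be > 0", "ihcmet_param_error")
  if (is.logical(reference)) reference <- which(reference)
  if (length(reference) != 1L || reference < 1 || reference > length(band))
    abort("exactly one reference sample required", "ihcmet_param_error")
  rel <- band / loading
  rel / rel[reference]
}

#' Generate a synthetic qPCR plate with known fold changes
#'
#' Reference-gene Cp is constant per sample up to noise; gene Cp values
#' are offset so the expected 2^ddCp of each non-control group versus the
#' control equals `true_fold_changes`.
#'
#' @param genes character vector of gene names.
#' @param groups character vector of condition labels; the first is the
#'   control.
#' @param true_fold_changes matrix (genes x groups) or vector recycled per
#'   gene of true fold changes (> 0); the control column is forced to 1.
#' @param cp_noise_sd Gaussian noise sd added to every Cp (>= 0).
#' @param n_replicates samples per group (default 3).
#' @param seed integer seed.
#' @param cp_reference_base,cp_gene_base baseline crossing points.
#' @return list: `records` data.frame (`sample_id`, `condition`, `gene`,
#'   `cp`, `cp_reference`) and `truth` (fold-change matrix).
#' @export
generate_qpcr <- function(genes, groups, true_fold_changes,
                          cp_noise_sd = 0, n_replicates = 3L, seed = 1L,
                          cp_reference_base = 10, cp_gene_base = 25) {
  check_pos(true_fold_changes, "true_fold_changes")
  check_pos(cp_noise_sd, "cp_noise_sd", strict = FALSE)
  ng <- length(genes); nk <- length(groups)
  fc <- matrix(true_fold_changes, ng, nk,
               dimnames = list(genes, groups))
  fc[, 1] <- 1
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        condition = groups, gene = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$sample_id <- paste(rows$condition, rows$replicate, sep = "_")
    n <- nrow(rows)
    # lower gene Cp = higher expression: cp = base - log2(fold)
    cp <- cp_gene_base - log2(fc[cbind(rows$gene, rows$condition)])
    noise <- if (cp_noise_sd > 0) rnorm(n, 0, cp_noise_sd) else 0
    ref_noise <- if (cp_noise_sd > 0) rnorm(n, 0, cp_noise_sd) else 0
    records <- data.frame(sample_id = rows$sample_id,
                          condition = rows$condition, gene = rows$gene,
                          cp = cp + noise,
                          cp_reference = cp_reference_base + ref_noise,
                          stringsAsFactors = FALSE)
    list(records = records, truth = fc)
  })
}
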