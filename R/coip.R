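#' Protein abundance matrix for label-free co-IP quantification
#'
#' Protein x (experiment, group) abundances from three independent
#' co-immunoprecipitation experiments with a bait (tagged) and a control
#' group. Missing values are allowed and handled later by the imputation
#' step. The object tracks its processing `stage` so the quantification chain
#' (presence filter, imputation, ratios, enrichment call) can only be applied
#' in the documented order.
#'
#' @param abundance numeric matrix, proteins in rows; column names must be
#'   `"e<experiment>.<group>"` with group `bait` or `control`
#'   (e.g. `e1.bait`, `e1.control`, ..., `e3.control`).
#' @param gene_symbol character vector of gene symbols, one per row.
#' @param accession optional accession per row.
#' @return An object of class `abundance_matrix` at stage `"raw"`.
#' @export
abundance_matrix <- function(abundance, gene_symbol = rownames(abundance),
                             accession = rownames(abundance)) {
  if (!is.matrix(abundance)) stop("abundance must be a matrix", call. = FALSE)
  cn <- colnames(abundance)
  if (is.null(cn) || !all(grepl("^e[0-9]+\\.(bait|control)$", cn)))
    stop("columns must be named e<experiment>.bait / e<experiment>.control",
         call. = FALSE)
  if (any(abundance <= 0, na.rm = TRUE))
    stop("abundances must be > 0 where present", call. = FALSE)
  structure(
    list(abundance = abundance, gene_symbol = gene_symbol,
         accession = accession,
         experiments = sort(unique(sub("\\..*$", "", cn))),
         stage = "raw"),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d proteins, experiments %s, stage '%s'\n",
              nrow(x$abundance), paste(x$experiments, collapse = "/"),
              x$stage))
  invisible(x)
}

coip_experiment_of <- function(cn) sub("\\..*$", "", cn)

#' TOP3 protein abundance from peptide intensities
#'
#' Label-free protein quantification in "TOP three" mode: for each (protein,
#' experiment, group) cell, the protein abundance is the mean of the three
#' highest peptide intensities. When fewer than three peptides were observed
#' the mean of those present is used (flagged in the result).
#'
#' @param peptides data.frame with columns `protein_id`, `gene_symbol`
#'   (optional), `peptide_id`, `experiment`, `group` (`"bait"`/`"control"`),
#'   `intensity` (>= 0 or NA for missing).
#' @return An [abundance_matrix]; attribute `"few_peptides"` is a logical
#'   matrix marking cells quantified from fewer than three peptides.
#' @export
top3_abundance <- function(peptides) {
  req <- c("protein_id", "peptide_id", "experiment", "group", "intensity")
  miss <- setdiff(req, names(peptides))
  if (length(miss))
    stop(sprintf("top3_abundance: missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(peptides) == 0) stop("top3_abundance: empty table", call. = FALSE)
  peptides <- peptides[!is.na(peptides$intensity), , drop = FALSE]
  prot <- sort(unique(peptides$protein_id))
  cells <- interaction(peptides$experiment, peptides$group, drop = FALSE)
  cols <- sort(unique(sprintf("e%s.%s", peptides$experiment, peptides$group)))
  ab <- matrix(NA_real_, nrow = length(prot), ncol = length(cols),
               dimnames = list(prot, cols))
  few <- matrix(FALSE, nrow = length(prot), ncol = length(cols),
                dimnames = list(prot, cols))
  key <- sprintf("e%s.%s", peptides$experiment, peptides$group)
  for (grp in split(seq_len(nrow(peptides)),
                    paste(peptides$protein_id, key, sep = "\r"))) {
    p <- peptides$protein_id[grp[1]]
    k <- key[grp[1]]
    ints <- sort(peptides$intensity[grp], decreasing = TRUE)
    ab[p, k] <- mean(utils::head(ints, 3))
    few[p, k] <- length(ints) < 3
  }
  gs <- if ("gene_symbol" %in% names(peptides)) {
    vapply(prot, function(p)
      as.character(peptides$gene_symbol[match(p, peptides$protein_id)]),
      character(1))
  } else prot
  out <- abundance_matrix(ab, gene_symbol = gs)
  attr(out, "few_peptides") <- few
  out
}

#' Replicate-presence filter
#'
#' Keeps only proteins quantified (non-missing in at least one group) in at
#' least `min_experiments` distinct experiments; the rest are dropped and
#' listed in the `"dropped"` attribute.
#'
#' @param mat an [abundance_matrix] at stage `"raw"`.
#' @param min_experiments minimum number of distinct experiments (default 2).
#' @return Filtered [abundance_matrix] at stage `"filtered"`.
#' @export
presence_filter <- function(mat, min_experiments = 2L) {
  if (mat$stage != "raw")
    stop("presence_filter: expected stage 'raw', got '", mat$stage, "'",
         call. = FALSE)
  exper <- coip_experiment_of(colnames(mat$abundance))
  n_exp_present <- apply(mat$abundance, 1, function(row)
    length(unique(exper[!is.na(row)])))
  keep <- n_exp_present >= min_experiments
  out <- mat
  out$abundance <- mat$abundance[keep, , drop = FALSE]
  out$gene_symbol <- mat$gene_symbol[keep]
  out$accession <- mat$accession[keep]
  out$stage <- "filtered"
  attr(out, "dropped") <- data.frame(
    protein_id = rownames(mat$abundance)[!keep],
    reason = sprintf("present in %d experiment(s), need >= %d",
                     n_exp_present[!keep], min_experiments),
    stringsAsFactors = FALSE)
  out
}

#' Minimum-abundance imputation
#'
#' Replaces every missing abundance in experiment `e` by the minimum observed
#' abundance of that experiment. By default the minimum is taken globally over
#' all proteins and both groups of the experiment (vendor behavior);
#' `scope = "group"` restricts it to the same group.
#'
#' @param mat an [abundance_matrix] at stage `"filtered"`.
#' @param scope `"experiment"` (default) or `"group"`.
#' @return Imputed [abundance_matrix] at stage `"imputed"`; no observed value
#'   is changed.
#' @export
impute_missing <- function(mat, scope = c("experiment", "group")) {
  scope <- match.arg(scope)
  if (mat$stage != "filtered")
    stop("impute_missing: expected stage 'filtered', got '", mat$stage, "'",
         call. = FALSE)
  ab <- mat$abundance
  cn <- colnames(ab)
  exper <- coip_experiment_of(cn)
  for (e in unique(exper)) {
    cols <- if (scope == "experiment") which(exper == e) else NULL
    for (j in which(exper == e)) {
      ref_cols <- if (scope == "experiment") cols else j
      vals <- ab[, ref_cols]
      if (all(is.na(vals)))
        stop("impute_missing: experiment ", e, " entirely missing",
             call. = FALSE)
      m <- min(vals, na.rm = TRUE)
      ab[is.na(ab[, j]), j] <- m
    }
  }
  out <- mat
  out$abundance <- ab
  out$stage <- "imputed"
  out
}

#' Per-experiment log2 bait/control abundance ratios
#'
#' Pairwise ratio-based quantification: for each protein and experiment,
#' `log2(bait abundance / control abundance)` after imputation.
#'
#' @param mat an [abundance_matrix] at stage `"imputed"`.
#' @return An `enrichment_result` data.frame with columns `gene_symbol`,
#'   `accession`, one `log2_R<e>` column per experiment, and placeholder
#'   `enriched`/`is_vatpase`/`is_bait` columns (NA until called/annotated).
#' @export
log2_ratios <- function(mat) {
  if (mat$stage != "imputed")
    stop("log2_ratios: expected stage 'imputed', got '", mat$stage, "'",
         call. = FALSE)
  ab <- mat$abundance
  if (any(is.na(ab)) || any(ab <= 0))
    stop("log2_ratios: abundances must be positive and complete", call. = FALSE)
  exps <- mat$experiments
  out <- data.frame(gene_symbol = mat$gene_symbol,
                    accession = mat$accession,
                    stringsAsFactors = FALSE)
  for (e in exps) {
    bait <- ab[, paste0(e, ".bait")]
    ctrl <- ab[, paste0(e, ".control")]
    out[[sub("^e", "log2_R", e)]] <- log2(bait / ctrl)
  }
  out$enriched <- NA
  out$is_vatpase <- NA
  out$is_bait <- NA
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Build an enrichment result directly from log2 ratios
#'
#' Entry point for tables that already carry per-experiment log2 bait/control
#' ratios (such as the packaged worked-example table).
#'
#' @param df data.frame with `gene_symbol`, optional `accession`, and
#'   `log2_R1`, `log2_R2`, ... columns.
#' @return An `enrichment_result`.
#' @export
enrichment_from_ratios <- function(df) {
  rc <- grep("^log2_R[0-9]+$", names(df), value = TRUE)
  if (length(rc) == 0)
    stop("enrichment_from_ratios: no log2_R<e> columns", call. = FALSE)
  out <- data.frame(gene_symbol = df$gene_symbol,
                    accession = if ("accession" %in% names(df)) df$accession
                                else df$gene_symbol,
                    stringsAsFactors = FALSE)
  for (cc in rc) out[[cc]] <- as.numeric(df[[cc]])
  out$enriched <- NA
  out$is_vatpase <- NA
  out$is_bait <- NA
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Call enrichment from per-experiment fold changes
#'
#' A protein is called enriched when its bait/control abundance ratio is at
#' least `fold_threshold` in every experiment, i.e. every `log2_R<e>` is
#' `>= log2(fold_threshold)` (inclusive boundary, matching "at least
#' 2-fold").
#'
#' @param result an `enrichment_result` (from [log2_ratios()] or
#'   [enrichment_from_ratios()]).
#' @param fold_threshold fold-change threshold (default 2).
#' @return The `enrichment_result` with the `enriched` column filled in.
#' @export
call_enriched <- function(result, fold_threshold = 2) {
  if (!inherits(result, "enrichment_result"))
    stop("call_enriched: need an enrichment_result", call. = FALSE)
  rc <- grep("^log2_R[0-9]+$", names(result), value = TRUE)
  thr <- log2(fold_threshold)
  ratios <- as.matrix(result[, rc, drop = FALSE])
  result$enriched <- apply(ratios, 1, function(r) all(is.finite(r) & r >= thr))
  result
}

#' Annotate enriched proteins against a V-ATPase subunit gene list
#'
#' Flags enriched proteins whose gene symbol matches the supplied subunit
#' list (or carries the `Vha` prefix). The immunoprecipitation bait is
#' flagged separately and excluded from the non-bait subunit count.
#'
#' @param result an `enrichment_result` with the `enriched` column filled.
#' @param subunit_genes character vector of V-ATPase subunit gene symbols;
#'   defaults to the bundled list (see [vatpase_gene_list()]).
#' @param bait gene symbol of the immunoprecipitation target
#'   (default `"CG31030"`).
#' @return The `enrichment_result` with `is_vatpase` and `is_bait` filled;
#'   attribute `"n_vatpase_nonbait"` holds the count of enriched non-bait
#'   subunits.
#' @export
annotate_vatpase <- function(result, subunit_genes = vatpase_gene_list(),
                             bait = "CG31030") {
  if (!inherits(result, "enrichment_result"))
    stop("annotate_vatpase: need an enrichment_result", call. = FALSE)
  if (any(is.na(result$enriched)))
    stop("annotate_vatpase: run call_enriched() first", call. = FALSE)
  gs <- result$gene_symbol
  in_list <- gs %in% subunit_genes |
    (length(subunit_genes) > 0 & startsWith(gs, "Vha"))
  result$is_bait <- gs == bait
  result$is_vatpase <- result$enriched & in_list & !result$is_bait
  attr(result, "n_vatpase_nonbait") <- sum(result$is_vatpase)
  result
}

#' Bundled V-ATPase subunit gene list
#'
#' Gene symbols of Drosophila V-ATPase constitutive and accessory subunits
#' (V1 and V0 domains plus accessory proteins), shipped with the package.
#'
#' @return Character vector of gene symbols.
#' @export
vatpase_gene_list <- function() {
  path <- system.file("extdata", "vatpase_genes.txt", package = "synaptoquant")
  genes <- readLines(path)
  genes[nzchar(genes) & !startsWith(genes, "#")]
}

#' Packaged co-IP worked example: 12-protein log2-ratio table
#'
#' Loads the bundled table of per-experiment log2 bait/control abundance
#' ratios for the 12 proteins enriched in all three co-immunoprecipitation
#' experiments of the worked example. Decimal commas in the source are
#' normalized to points on load.
#'
#' @return An `enrichment_result` with 12 rows and columns `log2_R1..3`.
#' @export
load_table3 <- function() {
  path <- system.file("extdata", "table3_log2_ratios.csv",
                      package = "synaptoquant")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (cc in grep("^log2_R", names(raw), value = TRUE))
    raw[[cc]] <- as.numeric(gsub(",", ".", raw[[cc]], fixed = TRUE))
  enrichment_from_ratios(raw)
}

#' Full enrichment chain from an abundance matrix
#'
#' Runs presence filtering, minimum-abundance imputation, log2 ratios,
#' enrichment calling and V-ATPase annotation in the enforced order.
#'
#' @param mat an [abundance_matrix] at stage `"raw"`.
#' @param fold_threshold see [call_enriched()].
#' @param subunit_genes,bait see [annotate_vatpase()].
#' @return Annotated `enrichment_result`.
#' @export
coip_enrichment_chain <- function(mat, fold_threshold = 2,
                                  subunit_genes = vatpase_gene_list(),
                                  bait = "CG31030") {
  res <- log2_ratios(impute_missing(presence_filter(mat)))
  annotate_vatpase(call_enriched(res, fold_threshold),
                   subunit_genes = subunit_genes, bait = bait)
}
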