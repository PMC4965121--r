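# Relative expression: the 2^-ddCt method on replicate Ct tables, and
# read-count expression profiles across libraries.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); per sample, ddCt is the
#' mean dCt minus the calibrator's mean dCt and the relative expression is
#' 2^-ddCt. The standard error is computed over replicate dCt values and
#' propagated to the expression scale (delta method), matching the
#' mean +/- SE presentation of qPCR bar plots.
#'
#' @param ct_table data.frame with columns `sample`, `gene_id`, `replicate`,
#'   `ct` (e.g. from [simulate_ct_table()] or [read_tsv()]).
#' @param target_gene gene to quantify (default: every non-reference gene).
#' @param reference_gene reference gene present in every sample (e.g.
#'   5S rRNA).
#' @param calibrator_sample sample whose expression defines 1.0.
#' @return data.frame with `sample`, `gene_id`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expression`, `se` (SE of the relative
#'   expression), `n_replicates`.
#' @export
ddct <- function(ct_table, target_gene = NULL, reference_gene,
                 calibrator_sample) {
  stopifnot(all(c("sample", "gene_id", "replicate", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  samples <- unique(ct_table$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  for (s in samples) {
    if (!any(ct_table$sample == s & ct_table$gene_id == reference_gene)) {
      stop("reference gene missing in sample: ", s)
    }
  }
  genes <- target_gene %||% setdiff(unique(ct_table$gene_id), reference_gene)
  delta_ct_reps <- function(g, s) {
    t_rows <- ct_table[ct_table$sample == s & ct_table$gene_id == g, ]
    r_rows <- ct_table[ct_table$sample == s & ct_table$gene_id == reference_gene, ]
    t_rows <- t_rows[order(t_rows$replicate), ]
    r_rows <- r_rows[order(r_rows$replicate), ]
    if (nrow(t_rows) == 0L) return(NULL)
    n <- min(nrow(t_rows), nrow(r_rows))
    t_rows$ct[seq_len(n)] - r_rows$ct[seq_len(n)]
  }
  rows <- list()
  for (g in genes) {
    cal <- delta_ct_reps(g, calibrator_sample)
    if (is.null(cal)) stop("target gene missing in calibrator: ", g)
    for (s in samples) {
      d <- delta_ct_reps(g, s)
      if (is.null(d)) next
      ddc <- mean(d) - mean(cal)
      rel <- 2^(-ddc)
      se_d <- if (length(d) > 1L) sd(d) / sqrt(length(d)) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene_id = g, delta_ct = mean(d), delta_delta_ct = ddc,
        rel_expression = rel, se = rel * log(2) * se_d,
        n_replicates = length(d), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-miRNA read-count profile across libraries
#'
#' @param hit_tables named list of data.frames (one per library), each with
#'   an id column and a count column (e.g. [identify_known()] output, or
#'   the `novel` table of [predict_novel()] with `id_col = "id"` and
#'   `count_col = "read_count"`).
#' @param id_col,count_col column names holding the miRNA id and the read
#'   count.
#' @return data.frame: one row per miRNA, one count column per library
#'   (0 where absent).
#' @export
count_profile <- function(hit_tables, id_col = "mirna_id", count_col = "count") {
  stopifnot(length(hit_tables) > 0L, !is.null(names(hit_tables)))
  per_lib <- lapply(hit_tables, function(df) {
    if (nrow(df) == 0L) return(setNames(integer(0), character(0)))
    tapply(df[[count_col]], df[[id_col]], sum)
  })
  ids <- sort(unique(unlist(lapply(per_lib, names))))
  out <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  for (lib in names(per_lib)) {
    v <- per_lib[[lib]][ids]
    v[is.na(v)] <- 0L
    out[[lib]] <- as.integer(v)
  }
  out
}
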