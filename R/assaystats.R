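#' Embryonic lethality and brood size from count tables
#'
#' Per worm, hatched and unhatched counts are summed over scoring windows
#' (e.g. 24-48 h and 48-72 h post-injection); lethality is
#' unhatched / (hatched + unhatched) and brood size their sum. Worms with a
#' zero total are excluded with a warning. Per condition, the mean, sample
#' standard deviation and range of per-worm lethality percentages are
#' reported with the number of worms and embryos.
#'
#' @param records data frame with columns `worm_id`, `condition`, `window`,
#'   `hatched`, `unhatched` (non-negative integers).
#' @return list with `per_worm` (data frame: `worm_id`, `condition`,
#'   `hatched`, `unhatched`, `brood_size`, `lethality_pct`) and
#'   `per_condition` (data frame: `condition`, `mean_lethality_pct`,
#'   `sd_lethality_pct`, `min_pct`, `max_pct`, `n_worms`, `n_embryos`).
#' @export
lethality <- function(records) {
  need <- c("worm_id", "condition", "window", "hatched", "unhatched")
  if (!all(need %in% names(records)))
    .stop_class(paste("records needs columns:", paste(need, collapse = ", ")),
                "nedyn_input_error")
  cnt <- c(records$hatched, records$unhatched)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    .stop_class("counts must be non-negative integers", "nedyn_input_error")
  agg <- stats::aggregate(cbind(hatched, unhatched) ~ worm_id + condition,
                          data = records, FUN = sum)
  agg$brood_size <- agg$hatched + agg$unhatched
  zero <- agg$brood_size == 0
  if (any(zero)) {
    warning(sprintf("excluding %d worm(s) with zero total counts", sum(zero)))
    agg <- agg[!zero, , drop = FALSE]
  }
  if (!nrow(agg)) .stop_class("no worms with non-zero totals", "nedyn_input_error")
  agg$lethality_pct <- 100 * agg$unhatched / agg$brood_size
  per_cond <- do.call(rbind, lapply(split(agg, agg$condition), function(g) {
    data.frame(condition = g$condition[1],
               mean_lethality_pct = mean(g$lethality_pct),
               sd_lethality_pct = if (nrow(g) > 1) sd(g$lethality_pct) else NA_real_,
               min_pct = min(g$lethality_pct), max_pct = max(g$lethality_pct),
               n_worms = nrow(g), n_embryos = sum(g$brood_size))
  }))
  rownames(per_cond) <- NULL
  list(per_worm = agg, per_condition = per_cond)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged per sample and gene first. For each
#' sample, delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct is taken
#' against the mean delta-Ct of the control condition, and the fold change
#' is 2^(-delta-delta-Ct). A plate-wide additive shift of a sample's Ct
#' values cancels in delta-Ct. The reference gene is a required argument
#' (assay designs differ in their housekeeping gene).
#'
#' @param ct_table data frame with columns `sample`, `condition`, `gene`,
#'   `ct`; replicate rows per (sample, gene) are technical replicates.
#' @param reference_gene housekeeping gene name.
#' @param control control condition label.
#' @param summary_mean `"arithmetic"` (default) or `"geometric"` mean of
#'   fold changes over biological replicates.
#' @return list with `per_sample` (data frame: `sample`, `condition`,
#'   `gene`, `delta_ct`, `delta_delta_ct`, `fold_change`) and `summary`
#'   (data frame: `gene`, `condition`, `mean_fold`, `sd_fold`, `n`).
#' @export
ddct <- function(ct_table, reference_gene, control,
                 summary_mean = c("arithmetic", "geometric")) {
  summary_mean <- match.arg(summary_mean)
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    .stop_class(paste("ct_table needs columns:", paste(need, collapse = ", ")),
                "nedyn_input_error")
  if (!control %in% ct_table$condition)
    .stop_class(sprintf("control condition '%s' not present", control),
                "nedyn_input_error")
  if (!reference_gene %in% ct_table$gene)
    .stop_class(sprintf("reference gene '%s' not present", reference_gene),
                "nedyn_input_error")
  # average technical replicates
  avg <- stats::aggregate(ct ~ sample + condition + gene, data = ct_table,
                          FUN = mean)
  ref <- avg[avg$gene == reference_gene, c("sample", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- avg[avg$gene != reference_gene, , drop = FALSE]
  merged <- merge(tgt, ref, by = "sample")
  dropped <- setdiff(tgt$sample, ref$sample)
  if (length(dropped))
    warning(sprintf("dropping sample(s) without reference Ct: %s",
                    paste(dropped, collapse = ", ")))
  if (!nrow(merged))
    .stop_class("no samples with both target and reference Ct", "nedyn_input_error")
  merged$delta_ct <- merged$ct - merged$ct_ref
  out <- do.call(rbind, lapply(split(merged, merged$gene), function(g) {
    ctrl_dct <- g$delta_ct[g$condition == control]
    if (!length(ctrl_dct))
      .stop_class(sprintf("no control samples for gene '%s'", g$gene[1]),
                  "nedyn_input_error")
    g$delta_delta_ct <- g$delta_ct - mean(ctrl_dct)
    g$fold_change <- 2^(-g$delta_delta_ct)
    g
  }))
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, list(out$gene, out$condition),
                                      drop = TRUE), function(g) {
    mf <- if (summary_mean == "arithmetic") mean(g$fold_change)
          else exp(mean(log(g$fold_change)))
    data.frame(gene = g$gene[1], condition = g$condition[1], mean_fold = mf,
               sd_fold = if (nrow(g) > 1) sd(g$fold_change) else NA_real_,
               n = nrow(g))
  }))
  rownames(summ) <- NULL
  list(per_sample = out[, c("sample", "condition", "gene", "delta_ct",
                            "delta_delta_ct", "fold_change")],
       summary = summ)
}
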