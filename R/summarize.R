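weighted_mode <- function(values, weights) {
  keep <- !is.na(values)
  if (!any(keep)) return(NA_integer_)
  agg <- tapply(weights[keep], values[keep], sum)
  cand <- as.integer(names(agg)[agg == max(agg)])
  min(cand)  # deterministic: smallest coordinate on ties
}

weighted_median <- function(values, weights) {
  keep <- !is.na(values)
  if (!any(keep)) return(NA_real_)
  median(rep(values[keep], weights[keep]))
}

#' Summarize junction calls per gene and treatment
#'
#' Aggregates [call_junctions()] output (one row per unique sequence, with a
#' `treatment` column distinguishing the deNADding enzyme used before
#' circularization) into the per-gene junction report: the top `k` junction
#' sequences with their support fractions, the predominant cap and 3'-end
#' sites per treatment, tail-length summaries, and whether the two cap
#' classes share a transcription start site.
#'
#' Support fractions are computed over junction-spanning reads (confidence
#' `high` or `low`) of the same gene and treatment. Predominant sites are the
#' support-weighted modes over high-confidence calls.
#'
#' @param calls Tibble from [call_junctions()] with an added `treatment`
#'   column.
#' @param k Number of top junction sequences per gene/treatment (default 5).
#' @param treatment_cap_map Named character vector mapping treatments to cap
#'   classes; the defaults mirror Rai1 deNADding (NAD caps) and the canonical
#'   decapping enzyme MDE (m7G caps).
#' @return List with `report` (top-k table; user-facing coordinates are
#'   1-based) and `gene_summary` (per gene: predominant sites per cap class,
#'   `same_tss`, polyA summaries).
#' @export
summarize_junctions <- function(calls, k = 5L,
                                treatment_cap_map = c(Rai1 = "NAD",
                                                      MDE = "m7G")) {
  stopifnot(all(c("gene_id", "treatment", "seq", "count", "cap_site",
                  "three_prime_site", "polya_len", "confidence")
                %in% names(calls)))
  calls <- tibble::as_tibble(calls)
  calls$cap_class <- unname(treatment_cap_map[calls$treatment])

  spanning <- calls[calls$confidence %in% c("high", "low"), , drop = FALSE]

  report <- spanning |>
    dplyr::group_by(.data$gene_id, .data$treatment) |>
    dplyr::mutate(total_support = sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  support_fraction = .data$count / .data$total_support,
                  cap_site_1based = .data$cap_site + 1L,
                  three_prime_site_1based = .data$three_prime_site + 1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "treatment", "rank", "seq", "count",
                  "support_fraction", "cap_site_1based",
                  "three_prime_site_1based", "polya_len", "confidence")

  high <- spanning[spanning$confidence == "high", , drop = FALSE]
  per_class <- high |>
    dplyr::group_by(.data$gene_id, .data$cap_class) |>
    dplyr::summarise(
      predominant_cap_site = weighted_mode(.data$cap_site, .data$count),
      predominant_3p_site = weighted_mode(.data$three_prime_site,
                                          .data$count),
      polya_len_median = weighted_median(.data$polya_len, .data$count),
      n_spanning = sum(.data$count), .groups = "drop")

  value_cols <- c("predominant_cap_site", "predominant_3p_site",
                  "polya_len_median", "n_spanning")
  gene_summary <- tidyr_pivot(per_class, value_cols)
  for (vc in value_cols) {
    for (cls in unique(stats::na.omit(unname(treatment_cap_map)))) {
      col <- paste0(vc, "_", cls)
      if (!col %in% names(gene_summary)) gene_summary[[col]] <- NA
    }
  }
  gene_summary$same_tss <-
    !is.na(gene_summary$predominant_cap_site_NAD) &
    !is.na(gene_summary$predominant_cap_site_m7G) &
    gene_summary$predominant_cap_site_NAD ==
      gene_summary$predominant_cap_site_m7G

  list(report = report, gene_summary = gene_summary)
}

# minimal wide reshape (cap_class -> column suffix) without a tidyr dependency
tidyr_pivot <- function(df, value_cols) {
  genes <- unique(df$gene_id)
  out <- tibble::tibble(gene_id = genes)
  for (cls in unique(df$cap_class)) {
    sub <- df[df$cap_class == cls, , drop = FALSE]
    idx <- match(genes, sub$gene_id)
    for (vc in value_cols) {
      out[[paste0(vc, "_", cls)]] <- sub[[vc]][idx]
    }
  }
  out
}

#' Run the full circNC junction pipeline for one gene
#'
#' Processes read 1, read 2 and the merged stream separately (junctions can
#' fall on either mate depending on unknown UTR lengths): polyA filtering
#' with orientation resolution, deduplication, junction calling, and cap-site
#' classification. The merged stream takes precedence in the per-gene
#' summary when it yields junction-spanning calls.
#'
#' @param read1,read2 Tibbles with `read_id`, `seq` (sequencing orientation).
#' @param model The gene's [transcript_model()].
#' @param treatment Treatment label for this library (e.g. `"Rai1"`,
#'   `"MDE"`).
#' @param scheme,min_flank,min_identity,min_polya,max_jumps Passed to
#'   [call_junctions()].
#' @param min_overlap,max_mismatch_frac Passed to [merge_pairs()].
#' @param k Top-k junction sequences for the report.
#' @return List with `calls` (all streams, `stream` column), `report`,
#'   `gene_summary` (single-treatment; see [summarize_junctions()] to combine
#'   treatments), `classification` (cap-site classes of high-confidence
#'   calls) and `log` (per-stream read counts through the stages).
#' @export
circnc_pipeline <- function(read1, read2, model, treatment,
                            scheme = scoring_scheme(), min_flank = 15L,
                            min_identity = 0.9, min_polya = 8L,
                            max_jumps = 3L, min_overlap = 12L,
                            max_mismatch_frac = 0.1, k = 5L) {
  merged <- merge_pairs(read1, read2, min_overlap, max_mismatch_frac)
  streams <- list(read1 = read1, read2 = read2, merged = merged)
  calls <- list()
  log <- list()
  for (nm in names(streams)) {
    rd <- streams[[nm]]
    passed <- filter_polya(rd, min_polya)
    cl <- call_junctions(passed, model, scheme, min_flank, min_identity,
                         min_polya, max_jumps)
    cl$stream <- rep(nm, nrow(cl))
    cl$treatment <- rep(treatment, nrow(cl))
    calls[[nm]] <- cl
    log[[nm]] <- tibble::tibble(
      stream = nm, n_input = nrow(rd), n_pass_filter = nrow(passed),
      n_unique = nrow(cl),
      n_high = sum(cl$count[cl$confidence == "high"]),
      n_low = sum(cl$count[cl$confidence == "low"]),
      n_none = sum(cl$count[cl$confidence == "none"]))
  }
  all_calls <- dplyr::bind_rows(calls)

  use <- all_calls[all_calls$stream == "merged", , drop = FALSE]
  if (!any(use$confidence %in% c("high", "low"))) {
    use <- all_calls[all_calls$stream %in% c("read1", "read2"), ,
                     drop = FALSE]
  }
  summ <- summarize_junctions(use, k = k)

  high <- use[use$confidence == "high" & !is.na(use$cap_site), ,
              drop = FALSE]
  classification <- if (nrow(high) > 0L) {
    sites <- unique(high$cap_site)
    dplyr::bind_rows(lapply(sites, function(s) {
      fake <- structure(list(gene_id = model$gene_id, cap_site = s,
                             confidence = "high"),
                        class = "junction_call")
      cbind(classify_cap_site(fake, model),
            support = sum(high$count[high$cap_site == s]))
    }))
  } else {
    tibble::tibble(gene_id = character(), cap_site = integer(),
                   ref_base = character(), category = character(),
                   support = integer())
  }

  list(calls = all_calls, report = summ$report,
       gene_summary = summ$gene_summary,
       classification = tibble::as_tibble(classification),
       log = dplyr::bind_rows(log))
}
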