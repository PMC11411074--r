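#' The five guide-selection rounds
#'
#' Successively relaxed criteria applied until the top `k` guides per
#' candidate promoter are held:
#'
#' | round | TSS distance | on-target | dangerous | off-target agg. | CFD max OT |
#' |-------|--------------|-----------|-----------|-----------------|------------|
#' | 1 | \[-150, -75\]  | >= 0.2 | <= 1 | > 80 | - |
#' | 2 | \[-400, -50\]  | >= 0.2 | <= 1 | > 80 | - |
#' | 3 | \[-400, -50\]  | >= 0.2 | <= 1 | > 50 | - |
#' | 4 | \[-400, -50\]  | >= 0.2 | <= 2 | > 50 | - |
#' | 5 | none           | >= 0.2 | <= 2 | > 10 | < 0.95 |
#'
#' Distances are signed and oriented by the target gene's strand (negative =
#' upstream of the TSS). Round 5 drops the distance constraint (encoded as
#' `NA` bounds) and adds the CFD ceiling.
#'
#' @return data.frame with one row per round.
#' @export
default_selection_rounds <- function() {
  data.frame(
    round = 1:5,
    dist_min = c(-150, -400, -400, -400, NA),
    dist_max = c(-75, -50, -50, -50, NA),
    min_on_target = 0.2,
    max_dangerous = c(1, 1, 1, 2, 2),
    min_off_target_agg = c(80, 80, 50, 50, 10),
    max_cfd = c(NA, NA, NA, NA, 0.95)
  )
}

#' Annotate candidates with signed TSS distance
#'
#' For each promoter, the reference TSS is the strongest CAGE peak within
#' +/-500 bp of the annotated TSS; ties go to the peak closest to the
#' annotated TSS (then to the smaller coordinate). Promoters with no peak in
#' range fall back to the annotated TSS. The distance of a candidate is its
#' signed offset from the reference TSS, oriented by the promoter strand so
#' that negative always means upstream; zero means the candidate overlaps the
#' TSS.
#'
#' @param candidates data.frame with `spacer`, `promoter_id`, `position`
#'   (0-based genomic position of the candidate) and score/flag columns (see
#'   [select_guides()]).
#' @param tss_peaks data.frame of promoters: `promoter_id`, `chrom`, `tss`
#'   (annotated position), `strand`.
#' @param cage_peaks data.frame of CAGE peaks: `chrom`, `position`, `signal`;
#'   may be empty.
#' @return `candidates` with a `tss_distance` column.
#' @export
annotate_tss_distance <- function(candidates, tss_peaks, cage_peaks = NULL) {
  missing_prom <- setdiff(candidates$promoter_id, tss_peaks$promoter_id)
  if (length(missing_prom)) {
    stop2("candidates reference unknown promoters: ",
          paste(missing_prom, collapse = ", "))
  }
  if (is.null(cage_peaks)) {
    cage_peaks <- data.frame(chrom = character(0), position = numeric(0),
                             signal = numeric(0))
  }
  ref <- vapply(seq_len(nrow(tss_peaks)), function(i) {
    tss <- tss_peaks$tss[i]
    near <- cage_peaks[cage_peaks$chrom == tss_peaks$chrom[i] &
                         abs(cage_peaks$position - tss) <= 500, , drop = FALSE]
    if (!nrow(near)) return(tss)
    near <- near[order(-near$signal, abs(near$position - tss), near$position), ,
                 drop = FALSE]
    near$position[1]
  }, numeric(1))
  names(ref) <- tss_peaks$promoter_id
  strand <- setNames(tss_peaks$strand, tss_peaks$promoter_id)
  off <- candidates$position - ref[candidates$promoter_id]
  candidates$tss_distance <- ifelse(strand[candidates$promoter_id] == "+", off, -off)
  candidates
}

round_pass <- function(candidates, round_row) {
  dist_ok <- if (is.na(round_row$dist_min)) TRUE else {
    !is.na(candidates$tss_distance) &
      candidates$tss_distance >= round_row$dist_min &
      candidates$tss_distance <= round_row$dist_max
  }
  cfd_ok <- if (is.na(round_row$max_cfd)) TRUE else candidates$cfd_max_ot < round_row$max_cfd
  dist_ok &
    candidates$on_target >= round_row$min_on_target &
    candidates$dangerous_in_genome <= round_row$max_dangerous &
    candidates$off_target_agg > round_row$min_off_target_agg &
    cfd_ok
}

#' Round-based guide selection
#'
#' Candidates flagged for polythymidine tracks or problematic GC content are
#' excluded outright. The rounds are then applied in order; within a round,
#' passing candidates are ranked by on-target score (descending), then by
#' absolute TSS distance (ascending), then lexicographically by spacer, and
#' admitted until `k` guides are held for the promoter. Selection is
#' deterministic and invariant to input row order. Promoters that exhaust all
#' rounds with fewer than `k` guides are reported in the `shortfall` table.
#'
#' @param candidates data.frame with columns `spacer`, `promoter_id`,
#'   `on_target` (in \[0,1\]), `off_target_agg` (in \[0,100\]),
#'   `dangerous_in_genome` (integer), `cfd_max_ot` (in \[0,1\]),
#'   `polyT_flag`, `gc_flag` (logical) and `tss_distance` (see
#'   [annotate_tss_distance()]).
#' @param rounds selection rounds, default [default_selection_rounds()].
#' @param k guides to select per promoter (default 4).
#' @return list with `selected` (columns of `candidates` plus `round`) and
#'   `shortfall` (promoter, n_selected) for under-filled promoters.
#' @export
select_guides <- function(candidates, rounds = default_selection_rounds(), k = 4) {
  stopifnot(k >= 1)
  need <- c("spacer", "promoter_id", "on_target", "off_target_agg",
            "dangerous_in_genome", "cfd_max_ot", "polyT_flag", "gc_flag",
            "tss_distance")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop2("candidate table missing columns: ", paste(miss, collapse = ", "))
  pool <- candidates[!(candidates$polyT_flag | candidates$gc_flag), , drop = FALSE]
  selected <- list()
  for (prom in sort(unique(candidates$promoter_id))) {
    cand <- pool[pool$promoter_id == prom, , drop = FALSE]
    held <- NULL
    for (ri in seq_len(nrow(rounds))) {
      if (!is.null(held) && nrow(held) >= k) break
      pass <- cand[round_pass(cand, rounds[ri, ]), , drop = FALSE]
      if (!is.null(held)) pass <- pass[!(pass$spacer %in% held$spacer), , drop = FALSE]
      if (!nrow(pass)) next
      pass <- pass[order(-pass$on_target, abs(pass$tss_distance), pass$spacer), ,
                   drop = FALSE]
      take <- head(pass, k - if (is.null(held)) 0 else nrow(held))
      take$round <- rounds$round[ri]
      held <- rbind(held, take)
    }
    if (!is.null(held)) selected[[prom]] <- held
  }
  sel <- if (length(selected)) do.call(rbind, selected) else
    cbind(candidates[0, , drop = FALSE], round = integer(0))
  rownames(sel) <- NULL
  n_sel <- table(factor(sel$promoter_id, levels = sort(unique(candidates$promoter_id))))
  short <- data.frame(promoter_id = names(n_sel), n_selected = as.integer(n_sel),
                      stringsAsFactors = FALSE)
  short <- short[short$n_selected < k, , drop = FALSE]
  rownames(short) <- NULL
  list(selected = sel, shortfall = short)
}
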