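#' Assign a composite zone-membership code
#'
#' A transcript is called specific to every zone where its one-vs-rest test
#' is significant (q-value at or below `alpha`) with positive log fold
#' change. The selected zones are listed highest normalized expression
#' first (ties broken by smaller p-value, then by the more anterior zone)
#' and joined with "." into the composite code: a transcript specific to
#' zones 1 and 2 with higher expression in zone 2 is coded `"2.1"`; with
#' higher expression in zone 1, `"1.2"`. A transcript specific to no zone
#' is coded `"none"`.
#'
#' @param records Test records for a single transcript: a data frame with
#'   one row per zone and columns `zone`, `logFC`, `p_value`, `q_value`.
#' @param cpm Named numeric vector of the transcript's normalized CPM, one
#'   entry per zone in axial order.
#' @param alpha FDR threshold; default 0.05.
#' @return A list of class `membership_code` with `zones` (character, may
#'   be empty) and `code` (string).
#' @examples
#' rec <- data.frame(zone = as.character(1:6),
#'                   logFC = c(2, 2.5, rep(-1, 4)),
#'                   p_value = c(1e-5, 1e-6, rep(0.8, 4)),
#'                   q_value = c(1e-4, 1e-5, rep(0.9, 4)))
#' cpm <- c(`1` = 80, `2` = 120, `3` = 5, `4` = 5, `5` = 5, `6` = 5)
#' assign_membership(rec, cpm)$code  # "2.1"
#' @export
assign_membership <- function(records, cpm, alpha = 0.05) {
  zones <- names(cpm)
  if (is.null(zones)) stop("cpm must be a named vector of zone CPMs")
  missing_z <- setdiff(zones, records$zone)
  if (length(missing_z) > 0)
    stop("missing test record for zone(s): ", paste(missing_z, collapse = ", "))
  if (anyDuplicated(records$zone) || nrow(records) != length(zones))
    stop("need exactly one test record per zone")
  ord <- match(zones, records$zone)  # axial order, independent of row order
  q <- records$q_value[ord]
  lfc <- records$logFC[ord]
  p <- records$p_value[ord]
  sel <- which(q <= alpha & lfc > 0)
  sel <- sel[order(-cpm[sel], p[sel], sel)]
  picked <- zones[sel]
  structure(list(zones = picked,
                 code = if (length(picked) == 0) "none"
                        else paste(picked, collapse = ".")),
            class = "membership_code")
}

#' @export
print.membership_code <- function(x, ...) {
  cat("membership code:", x$code, "\n")
  invisible(x)
}

#' Split a membership code back into its zone list
#'
#' @param code Code string such as `"2.1"` or `"none"`.
#' @return Character vector of zone labels (empty for `"none"`).
#' @export
membership_zones <- function(code) {
  if (identical(code, "none")) return(character(0))
  strsplit(code, ".", fixed = TRUE)[[1]]
}

#' Assign membership codes for all transcripts
#'
#' Vectorized driver over [assign_membership()]'s rule, applied to the full
#' output of [one_vs_rest_tests()].
#'
#' @param records A `zone_test_records` data frame covering all transcripts.
#' @param cpm Normalized CPM matrix on the same transcripts (rownames are
#'   transcript ids, colnames the zone labels).
#' @param alpha FDR threshold; default 0.05.
#' @return Data frame with `transcript_id` and `code`, in CPM row order.
#' @export
assign_membership_all <- function(records, cpm, alpha = 0.05) {
  ids <- rownames(cpm)
  zones <- colnames(cpm)
  n <- length(ids)
  gi <- match(records$transcript_id, ids)
  zi <- match(records$zone, zones)
  if (anyNA(gi) || anyNA(zi))
    stop("test records mention transcripts or zones absent from the CPM matrix")
  qm <- lm <- pm <- matrix(NA_real_, n, length(zones))
  idx <- cbind(gi, zi)
  qm[idx] <- records$q_value
  lm[idx] <- records$logFC
  pm[idx] <- records$p_value
  if (anyNA(qm)) stop("missing test record for some (transcript, zone) pair")
  codes <- character(n)
  for (g in seq_len(n)) {
    sel <- which(qm[g, ] <= alpha & lm[g, ] > 0)
    if (length(sel) == 0) {
      codes[g] <- "none"
    } else {
      sel <- sel[order(-cpm[g, sel], pm[g, sel], sel)]
      codes[g] <- paste(zones[sel], collapse = ".")
    }
  }
  data.frame(transcript_id = ids, code = codes, stringsAsFactors = FALSE)
}

#' Summarize membership categories
#'
#' Bins transcripts by their composite code and counts each distinct
#' category, mirroring the category summary of the zoned analysis (e.g.
#' "22 binning categories, of which 16 contain specificity to more than
#' one zone").
#'
#' @param codes Character vector of membership codes (including `"none"`),
#'   or the data frame from [assign_membership_all()].
#' @return An object of class `category_summary`: list with `counts` (named
#'   integer vector, count-descending then lexicographic, `"none"`
#'   included), `n_total`, `n_restricted` (transcripts with a non-"none"
#'   code), `n_categories` (distinct non-"none" codes) and `n_multi`
#'   (distinct codes naming more than one zone).
#' @export
summarize_categories <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$code
  tab <- table(codes)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(-counts, names(counts))]
  restricted <- setdiff(names(counts), "none")
  structure(list(counts = counts,
                 n_total = length(codes),
                 n_restricted = sum(counts[restricted]),
                 n_categories = length(restricted),
                 n_multi = sum(grepl(".", restricted, fixed = TRUE))),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(x$n_restricted, "of", x$n_total, "transcripts axially restricted in",
      x$n_categories, "categories (", x$n_multi, "multi-zone )\n")
  show <- utils::head(x$counts, 15)
  print(show)
  if (length(x$counts) > length(show)) cat("...\n")
  invisible(x)
}

#' Order transcripts for a zone heatmap
#'
#' Groups transcripts by their primary (first-listed) zone, anterior to
#' posterior, with unrestricted (`"none"`) transcripts last; within each
#' group transcripts are sorted by primary-zone CPM, descending. Also
#' returns the row-scaled CPM (each row divided by its maximum) used for
#' plotting.
#'
#' @param codes Data frame from [assign_membership_all()].
#' @param cpm Normalized CPM matrix on the same transcripts.
#' @return List with `order` (integer permutation of the rows) and `scaled`
#'   (row-scaled CPM in that order, values in \[0, 1\]).
#' @export
order_for_heatmap <- function(codes, cpm) {
  if (!identical(codes$transcript_id, rownames(cpm)))
    stop("codes and cpm must cover the same transcripts in the same order")
  zones <- colnames(cpm)
  primary <- vapply(codes$code, function(cd) {
    z <- membership_zones(cd)
    if (length(z) == 0) NA_character_ else z[1]
  }, character(1), USE.NAMES = FALSE)
  grp <- match(primary, zones)
  grp[is.na(grp)] <- length(zones) + 1  # "none" sorts last
  key_cpm <- ifelse(is.na(primary), 0, cpm[cbind(seq_len(nrow(cpm)),
                                                 match(primary, zones))])
  ord <- order(grp, -key_cpm)
  rmax <- apply(cpm, 1, max)
  scaled <- cpm / ifelse(rmax > 0, rmax, 1)
  list(order = ord, scaled = scaled[ord, , drop = FALSE])
}
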