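#' Correct a barcode block against a whitelist
#'
#' A block is corrected to the unique whitelist entry within Hamming
#' distance 1. Blocks more than a Hamming distance of 1 from every valid
#' block are unrecoverable (`"none"`); blocks at distance 1 from two or
#' more entries are `"ambiguous"` and are rejected rather than guessed.
#' Non-ACGT characters count as mismatches at their position.
#'
#' @param block a 6-nt character scalar.
#' @param whitelist character vector of valid blocks (all the same length).
#' @return list with `status` (`"ok"`, `"none"` or `"ambiguous"`) and
#'   `block` (the corrected block, or `NA` unless status is `"ok"`).
#' @export
correct_block <- function(block, whitelist) {
  stopifnot(nchar(block) == nchar(whitelist[1]))
  wl <- .wl_int(whitelist)
  res <- .correct_block_int(utf8ToInt(block), wl, whitelist)
  res
}

.wl_int <- function(whitelist) {
  matrix(unlist(lapply(whitelist, utf8ToInt), use.names = FALSE),
         nrow = length(whitelist), byrow = TRUE)
}

.correct_block_int <- function(block_int, wl_int, whitelist) {
  hit <- which(colSums(t(wl_int) != block_int) <= 1L)
  if (length(hit) == 0L) return(list(status = "none", block = NA_character_))
  if (length(hit) > 1L) {
    # exact match dominates distance-1 neighbours (identity is unambiguous)
    exact <- hit[colSums(t(wl_int[hit, , drop = FALSE]) != block_int) == 0L]
    if (length(exact) == 1L) return(list(status = "ok", block = whitelist[exact]))
    return(list(status = "ambiguous", block = NA_character_))
  }
  list(status = "ok", block = whitelist[hit])
}

#' Parse one tagged read into barcode, UMI and gene tag
#'
#' Applies the read-structure filters in order: the two linkers may deviate
#' from their expected length by at most 1 nt (located by enumerating the
#' nine length-offset combinations; substitutions inside linkers are not
#' counted); each of the three 6-nt barcode blocks must be within Hamming
#' distance 1 of a unique whitelist entry; the UMI between the ACG/GAC
#' flanks must be exactly 8 nt; and at most 1 mismatch is allowed across the
#' six flank positions (jointly by default). A read failing any constraint
#' is rejected with a reason in `{barcode_block, ambiguous_block, linker,
#' umi_length, flank_mismatch}`.
#'
#' @param sequence read sequence (character scalar).
#' @param whitelist character vector of valid barcode blocks.
#' @param layout a [default_layout()] list.
#' @param flank_scope `"joint"`: at most 1 mismatch over ACG+GAC together;
#'   `"per_flank"`: at most 1 in each.
#' @return list with `status` (`"parsed"` or `"rejected"`), and either
#'   `cell_barcode`/`umi`/`gene_tag` or `reason`.
#' @export
parse_read <- function(sequence, whitelist, layout = default_layout(),
                       flank_scope = c("joint", "per_flank")) {
  flank_scope <- match.arg(flank_scope)
  ctx <- demux_context(whitelist, layout, flank_scope)
  .parse_read_int(utf8ToInt(sequence), ctx)
}

# precomputed constants shared across reads
demux_context <- function(whitelist, layout, flank_scope = "joint") {
  list(
    wl = whitelist,
    wl_int = .wl_int(whitelist),
    wl_env = local({
      e <- new.env(hash = TRUE, size = length(whitelist) * 2L)
      for (w in whitelist) assign(w, w, envir = e)
      e
    }),
    B = layout$block_len,
    L1 = nchar(layout$linker1),
    L2 = nchar(layout$linker2),
    U = layout$umi_len,
    f5 = utf8ToInt(layout$umi_flank_5p),
    f3 = utf8ToInt(layout$umi_flank_3p),
    flank_scope = flank_scope,
    offsets = rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  )
}

# evaluate one (d1, d2) linker-offset candidate; returns a list describing
# how far the read got: blocks_ok, best UMI length, flank mismatch count,
# and the parsed fields when everything passes
.eval_candidate <- function(s, d1, d2, ctx) {
  B <- ctx$B
  p_b2 <- B + ctx$L1 + d1
  p_b3 <- p_b2 + B + ctx$L2 + d2
  P <- p_b3 + B                       # 0-based start of 5' flank
  n <- length(s)
  if (P + 3L + 7L + 3L + 1L > n) {    # flank + shortest UMI + flank + 1nt tag
    return(list(feasible = FALSE))
  }
  blocks <- vector("list", 3L)
  starts <- c(0L, p_b2, p_b3)
  for (k in 1:3) {
    bs <- s[(starts[k] + 1L):(starts[k] + B)]
    key <- intToUtf8(bs)
    exact <- get0(key, envir = ctx$wl_env, inherits = FALSE)
    blocks[[k]] <- if (!is.null(exact)) list(status = "ok", block = exact)
                   else .correct_block_int(bs, ctx$wl_int, ctx$wl)
  }
  status <- vapply(blocks, `[[`, "", "status")
  blocks_ok <- all(status == "ok")

  # locate the 3' flank: prefer a UMI of exactly 8 nt, allow 7/9 detection
  best_u <- NA_integer_; best_mm <- Inf; best_mm5 <- Inf; best_mm3 <- Inf
  mm5 <- sum(s[(P + 1L):(P + 3L)] != ctx$f5)
  for (u in c(ctx$U, ctx$U - 1L, ctx$U + 1L)) {
    q <- P + 3L + u
    if (q + 3L + 1L > n) next         # need flank + nonempty tag
    mm3 <- sum(s[(q + 1L):(q + 3L)] != ctx$f3)
    mm <- mm5 + mm3
    if (mm < best_mm) { best_mm <- mm; best_u <- u; best_mm5 <- mm5; best_mm3 <- mm3 }
  }
  flank_ok <- if (ctx$flank_scope == "joint") best_mm <= 1L
              else best_mm5 <= 1L && best_mm3 <= 1L
  valid <- blocks_ok && !is.na(best_u) && best_u == ctx$U && flank_ok
  out <- list(feasible = TRUE, blocks_ok = blocks_ok, block_status = status,
              best_u = best_u, flank_ok = flank_ok, valid = valid)
  if (valid) {
    out$cell_barcode <- paste0(blocks[[1]]$block, blocks[[2]]$block,
                               blocks[[3]]$block)
    q <- P + 3L + ctx$U
    out$umi <- intToUtf8(s[(P + 4L):q])
    out$gene_tag <- intToUtf8(s[(q + 4L):n])
  }
  out
}

.parse_read_int <- function(s, ctx) {
  cands <- vector("list", nrow(ctx$offsets))
  for (i in seq_len(nrow(ctx$offsets))) {
    cand <- .eval_candidate(s, ctx$offsets[i, 1L], ctx$offsets[i, 2L], ctx)
    if (isTRUE(cand$valid)) {
      return(list(status = "parsed", cell_barcode = cand$cell_barcode,
                  umi = cand$umi, gene_tag = cand$gene_tag))
    }
    cands[[i]] <- cand
  }
  list(status = "rejected", reason = .rejection_reason(s, cands, ctx))
}

.rejection_reason <- function(s, cands, ctx) {
  canon <- cands[[1L]]
  if (!isTRUE(canon$feasible)) return("umi_length")
  downstream <- function(cand) {
    if (is.na(cand$best_u) || cand$best_u != ctx$U) "umi_length" else "flank_mismatch"
  }
  if (canon$blocks_ok) return(downstream(canon))
  # canonical segmentation failed on the blocks; if a length-shifted
  # segmentation recovers them, the failure is downstream of the linkers
  for (i in 2:length(cands)) {
    if (isTRUE(cands[[i]]$feasible) && isTRUE(cands[[i]]$blocks_ok)) {
      return(downstream(cands[[i]]))
    }
  }
  # probe +/-2 linker deviations: correctable blocks there indicate a
  # linker-length violation rather than barcode corruption
  for (d1 in -2:2) for (d2 in -2:2) {
    if (max(abs(c(d1, d2))) == 2L) {
      cand <- .eval_candidate(s, d1, d2, ctx)
      if (isTRUE(cand$feasible) && isTRUE(cand$blocks_ok)) return("linker")
    }
  }
  if (any(canon$block_status == "none")) "barcode_block" else "ambiguous_block"
}

#' Parse a stream of reads
#'
#' Vectorized driver for [parse_read()]: every read yields exactly one
#' parsed record or one rejection record.
#'
#' @param reads data frame with columns `read_id` and `sequence` (as
#'   produced by [simulate_reads()] or [read_fastq()]).
#' @inheritParams parse_read
#' @return list with `parsed` (data frame: read_id, cell_barcode, umi,
#'   gene_tag) and `rejected` (data frame: read_id, reason).
#' @export
parse_reads <- function(reads, whitelist, layout = default_layout(),
                        flank_scope = c("joint", "per_flank")) {
  flank_scope <- match.arg(flank_scope)
  ctx <- demux_context(whitelist, layout, flank_scope)
  n <- nrow(reads)
  status <- character(n); bc <- character(n); umi <- character(n)
  tag <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    r <- .parse_read_int(utf8ToInt(reads$sequence[i]), ctx)
    status[i] <- r$status
    if (r$status == "parsed") {
      bc[i] <- r$cell_barcode; umi[i] <- r$umi; tag[i] <- r$gene_tag
    } else {
      reason[i] <- r$reason
    }
  }
  ok <- status == "parsed"
  list(
    parsed = data.frame(read_id = reads$read_id[ok], cell_barcode = bc[ok],
                        umi = umi[ok], gene_tag = tag[ok],
                        stringsAsFactors = FALSE),
    rejected = data.frame(read_id = reads$read_id[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE)
  )
}

#' Knee-based cell-calling threshold
#'
#' Cell-containing and ambient barcodes are separated on the distribution
#' of log10 total unique-transcript counts: a Gaussian kernel density
#' estimate of that distribution is bimodal (an ambient mode at low counts
#' and a cell mode at high counts), and the threshold is placed at the
#' density minimum between the two most prominent modes. Barcodes with
#' totals strictly above the threshold are called as cells. The method is
#' a pure function of the counts, so rescaling all counts by a constant
#' retains the same barcode set.
#'
#' @param barcode_counts numeric vector of per-barcode total transcript
#'   counts (>= 100 barcodes with positive counts required).
#' @return list with `threshold` (count value at the density valley),
#'   `rank` (number of barcodes above the threshold on the rank curve) and
#'   `n_retained` (barcodes called as cells, equal to `rank`).
#' @export
knee_cutoff <- function(barcode_counts) {
  counts <- barcode_counts[barcode_counts > 0]
  if (length(counts) < 100L) stop("need at least 100 barcodes", call. = FALSE)
  if (max(counts) == min(counts)) {
    stop("no knee: all barcode counts equal", call. = FALSE)
  }
  dens <- stats::density(log10(counts), n = 2048)
  y <- dens$y
  loc_max <- which(diff(sign(diff(y))) == -2L) + 1L
  if (length(loc_max) < 2L) {
    stop("no knee: barcode count distribution is unimodal", call. = FALSE)
  }
  # secondary mode chosen by prominence (height above the deepest valley
  # separating it from the global mode), so minor ripples on the dominant
  # mode are never mistaken for the cell population
  gm <- loc_max[which.max(y[loc_max])]
  cands <- setdiff(loc_max, gm)
  prominence <- vapply(cands, function(c) {
    y[c] - min(y[min(c, gm):max(c, gm)])
  }, numeric(1))
  sec <- cands[which.max(prominence)]
  if (max(prominence) <= 0) {
    stop("no knee: barcode count distribution is unimodal", call. = FALSE)
  }
  lo <- min(gm, sec); hi <- max(gm, sec)
  valley <- lo + which.min(y[lo:hi]) - 1L
  thr <- 10^dens$x[valley]
  n_ret <- sum(counts > thr)
  list(threshold = thr, rank = n_ret, n_retained = n_ret)
}

#' Deduplicate parsed reads into a UMI count matrix
#'
#' PCR duplicates are removed in per-gene mode: the count for a
#' (cell, gene) pair is the number of distinct UMI sequences observed for
#' that pair, so the same UMI seen under two different genes contributes
#' once to each gene. Invariant to read duplication and read order.
#'
#' @param parsed data frame with columns `cell_barcode`, `umi`, `gene_tag`.
#' @return integer gene x cell-barcode count matrix (rows and columns in
#'   sorted order).
#' @export
dedup_count <- function(parsed) {
  if (nrow(parsed) == 0) return(matrix(0L, 0, 0))
  key <- paste(parsed$cell_barcode, parsed$gene_tag, parsed$umi, sep = "\r")
  uniq <- parsed[!duplicated(key), c("cell_barcode", "gene_tag")]
  genes <- sort(unique(uniq$gene_tag))
  cells <- sort(unique(uniq$cell_barcode))
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  tab <- table(factor(uniq$gene_tag, levels = genes),
               factor(uniq$cell_barcode, levels = cells))
  m[] <- as.integer(tab)
  m
}
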