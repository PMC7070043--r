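# Independent brute-force oracles, coded naively on purpose: plain loops
# and character vectors, no shared code with the package internals.

# Hamming distance between two equal-length character vectors of single chars
.o_ham <- function(a, b) sum(a != b)

# Brute-force read-rule checker. Enumerates linker-length offsets and UMI
# lengths in the same preference order the demultiplexer documents, and
# applies each filter by direct definition: blocks within Hamming distance 1
# of a unique whitelist entry (identity beats distance-1 neighbours), UMI of
# exactly 8 nt between the flanks, and at most 1 mismatch over the six flank
# positions (joint scope). Returns accept/reject plus the parsed fields.
oracle_parse_read <- function(sequence, whitelist, layout = dexhet::default_layout()) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  wl_ch <- lapply(whitelist, function(w) strsplit(w, "", fixed = TRUE)[[1]])
  B <- layout$block_len
  L1 <- nchar(layout$linker1); L2 <- nchar(layout$linker2)
  f5 <- strsplit(layout$umi_flank_5p, "", fixed = TRUE)[[1]]
  f3 <- strsplit(layout$umi_flank_3p, "", fixed = TRUE)[[1]]

  correct <- function(block_ch) {
    dists <- vapply(wl_ch, function(w) .o_ham(block_ch, w), numeric(1))
    if (any(dists == 0)) return(whitelist[which(dists == 0)[1]])
    ok <- which(dists == 1)
    if (length(ok) == 1) return(whitelist[ok])
    NA_character_
  }

  offsets <- list(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                  c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (off in offsets) {
    d1 <- off[1]; d2 <- off[2]
    p1 <- 1
    p2 <- p1 + B + L1 + d1
    p3 <- p2 + B + L2 + d2
    pf <- p3 + B                       # start of 5' flank
    if (pf + 2 + 7 + 3 + 1 > length(ch)) next
    b1 <- correct(ch[p1:(p1 + B - 1)])
    b2 <- correct(ch[p2:(p2 + B - 1)])
    b3 <- correct(ch[p3:(p3 + B - 1)])
    mm5 <- .o_ham(ch[pf:(pf + 2)], f5)
    best_u <- NA; best_mm <- Inf
    for (u in c(8, 7, 9)) {
      q <- pf + 3 + u
      if (q + 2 + 1 > length(ch)) next
      mm <- mm5 + .o_ham(ch[q:(q + 2)], f3)
      if (mm < best_mm) { best_mm <- mm; best_u <- u }
    }
    if (!is.na(b1) && !is.na(b2) && !is.na(b3) &&
        !is.na(best_u) && best_u == 8 && best_mm <= 1) {
      q <- pf + 3 + 8
      return(list(accept = TRUE,
                  cell_barcode = paste0(b1, b2, b3),
                  umi = paste(ch[(pf + 3):(pf + 10)], collapse = ""),
                  gene_tag = paste(ch[(q + 3):length(ch)], collapse = "")))
    }
  }
  list(accept = FALSE)
}

# All-pairs TSS/peak proximity scan
oracle_proximity <- function(tss, peaks, window = 50000) {
  out <- integer(nrow(tss))
  names(out) <- tss$gene_id
  for (i in seq_len(nrow(tss))) {
    cnt <- 0L
    for (j in seq_len(nrow(peaks))) {
      if (tss$chrom[i] != peaks$chrom[j]) next
      s <- peaks$start[j]; e <- peaks$end[j] - 1L
      d <- if (tss$pos[i] < s) s - tss$pos[i]
           else if (tss$pos[i] > e) tss$pos[i] - e
           else 0L
      if (d <= window) cnt <- cnt + 1L
    }
    out[i] <- min(cnt, 2L)
  }
  out
}

# Pearson correlation from the covariance formula, one pair at a time
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Random corruption of a structured read: substitutions anywhere plus
# occasional single-base insertions/deletions in the linkers or UMI
corrupt_read <- function(sequence, n_sub, indel = c("none", "del", "ins"),
                         indel_pos = NULL) {
  indel <- match.arg(indel)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    pos <- sample.int(length(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  if (indel == "del") {
    p <- if (is.null(indel_pos)) sample.int(length(ch) - 1, 1) else indel_pos
    ch <- ch[-p]
  } else if (indel == "ins") {
    p <- if (is.null(indel_pos)) sample.int(length(ch) - 1, 1) else indel_pos
    ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = p)
  }
  paste(ch, collapse = "")
}

# Compact simulation fixtures used across test files
tiny_config <- function(responder_prob = c(0, 0.2, 0.5), seed = 11, ...) {
  dexhet::sim_config(n_genes = 60, cells_per_timepoint = 25,
                     timepoints = c("0h", "1h", "18h"),
                     time_hours = c(0, 1, 18),
                     responder_prob = responder_prob,
                     seed = seed, ...)
}

# build a hand-specified truth object for formula-level checks
manual_truth <- function(mu, fold_change, direction, kinetic,
                         timepoints = c("0h", "18h"), hours = c(0, 18),
                         responder_prob = c(0, 0.5), phi = 0.5,
                         config = NULL) {
  n <- length(mu)
  if (is.null(config)) {
    config <- dexhet::sim_config(n_genes = n, timepoints = timepoints,
                                 time_hours = hours,
                                 responder_prob = responder_prob,
                                 cells_per_timepoint = 50, seed = 3)
  }
  structure(list(
    genes = data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                       mu = mu, phi = phi,
                       is_deg = fold_change != 1,
                       direction = direction, kinetic = kinetic,
                       fold_change = fold_change, stringsAsFactors = FALSE),
    timepoints = data.frame(timepoint = timepoints, hours = hours,
                            responder_prob = responder_prob,
                            stringsAsFactors = FALSE),
    config = config
  ), class = "dex_truth")
}

# wrap a bare matrix as a dex_norm object (log-scale values as supplied)
as_norm <- function(mat, timepoint = rep("0h", ncol(mat))) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%04d", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  structure(list(mat = mat, scale = 10000, log_base = "e",
                 cell_meta = data.frame(cell = colnames(mat),
                                        timepoint = timepoint,
                                        stringsAsFactors = FALSE)),
            class = "dex_norm")
}
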