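#' Default tagged-read layout
#'
#' The combinatorial cell barcode is three 6-nt blocks separated by two
#' fixed linker sequences; the 8-nt UMI is flanked by ACG (5') and GAC (3'),
#' and the remainder of the read is an opaque gene tag. The linker
#' sequences of the commercial kit are not public; these defaults are
#' arbitrary fixed strings and are configurable.
#'
#' @param linker1,linker2 fixed linker sequences between barcode blocks.
#' @return list describing the read layout.
#' @export
default_layout <- function(linker1 = "TAGCCATCGCATTGC",
                           linker2 = "TACCTCTGAGCTGAA") {
  list(block_len = 6L, n_blocks = 3L,
       linker1 = linker1, linker2 = linker2,
       umi_flank_5p = "ACG", umi_flank_3p = "GAC",
       umi_len = 8L)
}

#' Generate a barcode whitelist
#'
#' Greedily samples 6-nt blocks over ACGT with pairwise Hamming distance
#' >= 3, so that single-mismatch correction is always unambiguous.
#'
#' @param n number of blocks.
#' @param block_len block length in nt.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed RNG seed.
#' @return character vector of barcode blocks.
#' @export
make_whitelist <- function(n = 96, block_len = 6L, min_dist = 3L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  out_mat <- matrix(integer(0), nrow = 0, ncol = block_len)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200000L) stop("could not build whitelist; lower n or min_dist")
    cand <- sample.int(4L, block_len, replace = TRUE)
    if (nrow(out_mat) == 0 ||
        all(rowSums(out_mat != rep(cand, each = nrow(out_mat))) >= min_dist)) {
      out_mat <- rbind(out_mat, cand)
      out <- c(out, paste(bases[cand], collapse = ""))
    }
  }
  out
}

#' Simulate tagged reads from a count matrix
#'
#' Emits one read record per (cell, gene, molecule) occurrence (times
#' `1 + Pois(dup_rate)` PCR duplicates). Each molecule carries a UMI drawn
#' without replacement within its (cell, gene) pair, so an error-free
#' round trip through parsing and deduplication reproduces the count matrix
#' exactly. With `error_rate > 0`, per-base substitutions are injected into
#' the barcode blocks, linkers and UMI flanks (not the UMI or gene tag),
#' and the number injected per read is recorded.
#'
#' @param sim a [simulate_counts()] object (or any list with `counts`).
#' @param whitelist character vector of valid barcode blocks.
#' @param layout a [default_layout()] list.
#' @param error_rate per-base substitution probability in the structured
#'   prefix of the read.
#' @param dup number of extra PCR duplicate reads per molecule (each
#'   molecule yields `1 + dup` reads sharing one UMI).
#' @param seed RNG seed.
#' @return list with `reads` (data frame: read_id, sequence), `truth`
#'   (data frame: read_id, cell, gene, umi, n_errors) and `barcode_of_cell`
#'   (named character vector mapping cell id to its 18-nt barcode).
#' @export
simulate_reads <- function(sim, whitelist, layout = default_layout(),
                           error_rate = 0, dup = 0, seed = 1L) {
  counts <- sim$counts
  n_cells <- ncol(counts)
  W <- length(whitelist)
  if (W^3 < n_cells) stop("more cells than barcode combinations", call. = FALSE)
  set.seed(seed)

  # assign each cell a unique barcode triple by mixed-radix enumeration
  idx <- sample.int(W^3, n_cells) - 1L
  b1 <- whitelist[idx %% W + 1L]
  b2 <- whitelist[(idx %/% W) %% W + 1L]
  b3 <- whitelist[(idx %/% (W * W)) %% W + 1L]
  barcode_of_cell <- paste0(b1, b2, b3)
  names(barcode_of_cell) <- colnames(counts)

  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    return(list(reads = data.frame(read_id = character(0), sequence = character(0)),
                truth = data.frame(read_id = character(0), cell = character(0),
                                   gene = character(0), umi = character(0),
                                   n_errors = integer(0)),
                barcode_of_cell = barcode_of_cell))
  }
  n_mol_per <- counts[nz]
  umi_space <- 4L^layout$umi_len

  mol_cell <- rep(nz[, 2L], n_mol_per)
  mol_gene <- rep(nz[, 1L], n_mol_per)
  # distinct UMIs within each (cell, gene) pair
  umi_int <- unlist(lapply(n_mol_per, function(k) sample.int(umi_space, k) - 1L),
                    use.names = FALSE)
  umi <- int_to_seq(umi_int, layout$umi_len)

  per_mol <- 1L + as.integer(dup)
  read_cell <- rep(mol_cell, each = per_mol)
  read_gene <- rep(mol_gene, each = per_mol)
  read_umi <- rep(umi, each = per_mol)

  cell_ids <- colnames(counts)[read_cell]
  gene_ids <- rownames(counts)[read_gene]
  prefix <- paste0(b1[read_cell], layout$linker1, b2[read_cell],
                   layout$linker2, b3[read_cell])
  n_reads <- length(prefix)
  read_id <- sprintf("r%07d", seq_len(n_reads))

  n_errors <- integer(n_reads)
  f5 <- rep(layout$umi_flank_5p, n_reads)
  f3 <- rep(layout$umi_flank_3p, n_reads)
  if (error_rate > 0) {
    # substitutions in the structured region only: blocks + linkers + flanks
    region_len <- nchar(prefix[1]) + 6L
    for (i in seq_len(n_reads)) {
      nerr <- stats::rbinom(1L, region_len, error_rate)
      if (nerr > 0) {
        chars <- strsplit(paste0(prefix[i], f5[i], f3[i]), "", fixed = TRUE)[[1]]
        pos <- sample.int(length(chars), nerr)
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
        np <- length(chars) - 6L
        prefix[i] <- paste(chars[seq_len(np)], collapse = "")
        f5[i] <- paste(chars[np + 1:3], collapse = "")
        f3[i] <- paste(chars[np + 4:6], collapse = "")
        n_errors[i] <- nerr
      }
    }
  }

  sequence <- paste0(prefix, f5, read_umi, f3, gene_ids)
  list(reads = data.frame(read_id = read_id, sequence = sequence,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = read_id, cell = cell_ids, gene = gene_ids,
                          umi = read_umi, n_errors = n_errors,
                          stringsAsFactors = FALSE),
       barcode_of_cell = barcode_of_cell)
}

int_to_seq <- function(x, len) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = len, ncol = length(x))
  for (i in seq_len(len)) {
    out[i, ] <- bases[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(out, 2L, paste, collapse = "")
}
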