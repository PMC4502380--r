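#' Read a per-F2 x per-SNP allele count table
#'
#' Long-format TSV with header `f2, scaffold, pos, m_reads, f_reads`,
#' plus a two-column sidecar (`f2, total_reads`) of per-F2 total mapped
#' reads. Duplicate (f2, SNP) rows, negative counts and malformed rows
#' are rejected with the offending line number.
#'
#' @param path count-table TSV.
#' @param totals_path per-F2 totals TSV.
#' @return an [allele_counts()] object.
#' @export
read_count_table <- function(path, totals_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("f2", "scaffold", "pos", "m_reads", "f_reads")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  for (col in c("pos", "m_reads", "f_reads")) {
    bad <- which(is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("malformed %s at line %d of %s", col, bad[1] + 1, path))
  }
  neg <- which(df$m_reads < 0 | df$f_reads < 0)
  if (length(neg) > 0)
    stop(sprintf("negative read count at line %d of %s", neg[1] + 1, path))
  tot <- utils::read.delim(totals_path, stringsAsFactors = FALSE)
  if (!all(c("f2", "total_reads") %in% names(tot)))
    stop("totals sidecar must have columns f2, total_reads")
  key <- paste(df$f2, df$scaffold, df$pos)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("duplicate (f2, SNP) row at line %d of %s", dup[1] + 1, path))
  snps <- unique(df[c("scaffold", "pos")])
  snps <- snps[order(snps$scaffold, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  f2s <- tot$f2
  si <- match(paste(df$scaffold, df$pos), paste(snps$scaffold, snps$pos))
  fi <- match(df$f2, f2s)
  if (any(is.na(fi)))
    stop("count table contains F2 ids missing from the totals sidecar")
  m <- matrix(0L, nrow(snps), length(f2s))
  f <- matrix(0L, nrow(snps), length(f2s))
  m[cbind(si, fi)] <- as.integer(df$m_reads)
  f[cbind(si, fi)] <- as.integer(df$f_reads)
  allele_counts(snps, m, f, tot$total_reads, f2s)
}

#' Write an allele count table (and totals sidecar)
#'
#' Inverse of [read_count_table()]; only non-zero entries are written.
#'
#' @param counts an [allele_counts()] object.
#' @param path,totals_path output TSV paths.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(counts, path, totals_path) {
  nz <- which(counts$m > 0 | counts$f > 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2], nz[, 1]), , drop = FALSE]
  df <- data.frame(f2 = counts$f2[nz[, 2]],
                   scaffold = counts$snps$scaffold[nz[, 1]],
                   pos = counts$snps$pos[nz[, 1]],
                   m_reads = counts$m[nz], f_reads = counts$f[nz])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(f2 = counts$f2, total_reads = counts$totals),
                     totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scaffold-length index
#'
#' Two-column name/length table (a `.fai`-compatible subset: extra
#' columns are ignored).
#'
#' @param path TSV path (no header).
#' @return named numeric vector of lengths.
#' @export
read_scaffold_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("scaffold index needs at least name and length columns")
  if (any(df[[2]] <= 0)) stop("non-positive scaffold length in ", path)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

# R/qtl csv genotype codes: A,H,B = MM,MF,FF; D = not-FF (MM/MF),
# C = not-MM (MF/FF); "-" missing. Haploid M/F export as A/B.
RQTL_CODE <- c(MM = "A", MF = "H", FF = "B", `MM/MF` = "D", `MF/FF` = "C",
               M = "A", F = "B")

#' Export genotypes + map + phenotypes as an R/qtl "csv" cross file
#'
#' First columns are phenotypes, then one column per mapped marker with
#' chromosome and cM header rows, genotype codes A/H/B/D/C/-.
#' Markers without a map position are excluded with a warning.
#'
#' @param geno a `bin_geno` object.
#' @param map a `linkage_map`.
#' @param phenotypes data.frame of per-F2 phenotypes (rows matching
#'   `geno$f2`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rqtl_csv <- function(geno, map, phenotypes, path) {
  idx <- match(map$marker, rownames(geno$calls))
  missing_map <- setdiff(rownames(geno$calls), map$marker)
  if (length(missing_map) > 0)
    warning(length(missing_map), " marker(s) without map position excluded")
  codes <- matrix(RQTL_CODE[geno$calls[idx, , drop = FALSE]],
                  nrow = length(idx))
  codes[is.na(codes)] <- "-"
  ph <- as.data.frame(phenotypes)
  # chromosome ids must be numeric-ish for R/qtl; strip the LG prefix
  chrom <- sub("^LG", "", map$group)
  header <- c(names(ph), map$marker)
  row_chr <- c(rep("", ncol(ph)), chrom)
  row_cm <- c(rep("", ncol(ph)), format(round(map$cM, 3), trim = TRUE))
  body <- cbind(as.matrix(format(ph, trim = TRUE)), t(codes))
  lines <- c(paste(header, collapse = ","),
             paste(row_chr, collapse = ","),
             paste(row_cm, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read back an R/qtl "csv" cross file
#'
#' Minimal re-parser used for round-trip validation of
#' [write_rqtl_csv()] output.
#'
#' @param path csv path.
#' @param n_pheno number of leading phenotype columns.
#' @return list with `phenotypes`, `markers` (marker, chromosome, cM)
#'   and `calls` (markers x F2s character matrix in MM/MF/FF/
#'   MM\\/MF/MF\\/FF/NA vocabulary).
#' @export
read_rqtl_csv <- function(path, n_pheno = 1) {
  lines <- readLines(path)
  split1 <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  header <- split1(lines[1]); chrom <- split1(lines[2]); cm <- split1(lines[3])
  pcols <- seq_len(n_pheno)
  mk <- data.frame(marker = header[-pcols], chromosome = chrom[-pcols],
                   cM = as.numeric(cm[-pcols]), stringsAsFactors = FALSE)
  body <- do.call(rbind, lapply(lines[-(1:3)], split1))
  ph <- as.data.frame(body[, pcols, drop = FALSE], stringsAsFactors = FALSE)
  names(ph) <- header[pcols]
  inv <- c(A = "MM", H = "MF", B = "FF", D = "MM/MF", C = "MF/FF")
  calls <- t(apply(body[, -pcols, drop = FALSE], 1, function(r) inv[r]))
  calls <- t(calls)
  dimnames(calls) <- list(mk$marker, NULL)
  list(phenotypes = ph, markers = mk, calls = calls)
}

#' Write a placement as AGP v2.0
#'
#' One `W` line per placed scaffold (strand `+`, `-`, or `?` for unknown
#' orientation) separated by `U` gap lines of fixed size (gap type
#' "scaffold", linkage "yes", evidence "map").
#'
#' @param placements placement data.frame (`scaffold`, `chromosome`,
#'   `rank`, `orientation`).
#' @param scaffold_lengths named vector of lengths.
#' @param path output path.
#' @param gap_bp gap size between consecutive scaffolds.
#' @return invisibly, `path`.
#' @export
write_agp <- function(placements, scaffold_lengths, path, gap_bp = 1000) {
  lines <- c("##agp-version\t2.0")
  for (cn in unique(placements$chromosome[!is.na(placements$chromosome)])) {
    p <- placements[!is.na(placements$chromosome) & placements$chromosome == cn, ]
    p <- p[order(p$rank), ]
    pos <- 0; part <- 0
    for (i in seq_len(nrow(p))) {
      L <- scaffold_lengths[[p$scaffold[i]]]
      if (is.null(L)) stop("no length for scaffold ", p$scaffold[i])
      if (i > 1) {
        part <- part + 1
        lines <- c(lines, paste(cn, pos + 1, pos + gap_bp, part, "U", gap_bp,
                                "scaffold", "yes", "map", sep = "\t"))
        pos <- pos + gap_bp
      }
      part <- part + 1
      strand <- switch(p$orientation[i], `+` = "+", `-` = "-", "?")
      lines <- c(lines, paste(cn, pos + 1, pos + L, part, "W", p$scaffold[i],
                              1, L, strand, sep = "\t"))
      pos <- pos + L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Re-parse an AGP v2.0 file
#'
#' @param path AGP path.
#' @return data.frame of component (`W`) and gap (`U`) lines with
#'   coordinates; validates that object coordinates are contiguous.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  df <- data.frame(object = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)),
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   part = as.integer(vapply(parts, `[`, "", 4)),
                   type = vapply(parts, `[`, "", 5),
                   comp = vapply(parts, `[`, "", 6),
                   comp_start = vapply(parts, `[`, "", 7),
                   comp_end = vapply(parts, `[`, "", 8),
                   strand = vapply(parts, function(p)
                     if (length(p) >= 9) p[9] else NA_character_, ""),
                   stringsAsFactors = FALSE)
  for (cn in unique(df$object)) {
    d <- df[df$object == cn, ]
    d <- d[order(d$part), ]
    if (d$start[1] != 1 || any(d$start[-1] != d$end[-nrow(d)] + 1))
      stop("non-contiguous AGP object coordinates for ", cn)
  }
  df
}

#' Read / write a pipeline run configuration
#'
#' JSON round-trip of a nested configuration (sieve, binning, genotype,
#' HMM and scan parameters plus paths and seed). Unknown top-level keys
#' are rejected.
#'
#' @param path JSON path.
#' @return for `read_run_config()`: the configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("paths", "sieve", "binning", "genotype", "hmm", "scan",
             "sim", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
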