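#' Orient a scaffold from its markers' map positions
#'
#' The orientation is the sign of the rank correlation between marker
#' physical position within the scaffold (bp) and genetic position (cM).
#' Scaffolds with fewer than two markers at distinct cM, or zero
#' correlation, are "unknown" -- the typical fate of small scaffolds
#' covered by a single bin.
#'
#' @param bp physical positions of the scaffold's markers (bp within
#'   scaffold).
#' @param cM their genetic positions on one map.
#' @return `"+"`, `"-"` or `"unknown"`.
#' @export
orient_scaffold <- function(bp, cM) {
  ok <- !is.na(bp) & !is.na(cM)
  bp <- bp[ok]; cM <- cM[ok]
  if (length(bp) < 2 || length(unique(cM)) < 2 || length(unique(bp)) < 2)
    return("unknown")
  rho <- stats::cor(bp, cM, method = "spearman")
  if (is.na(rho) || rho == 0) return("unknown")
  if (rho > 0) "+" else "-"
}

# longest increasing subsequence, O(n^2) (internal; used to isolate the
# minimal set of scaffolds whose relocation explains an order change)
lis_members <- function(x) {
  n <- length(x)
  if (n == 0) return(logical(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (x[j] < x[i] && len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; prev[i] <- j }
  }
  i <- which.max(len)
  keep <- logical(n)
  while (i > 0) { keep[i] <- TRUE; i <- prev[i] }
  keep
}

#' Anchor and orient scaffolds from a linkage map
#'
#' Each scaffold with mapped markers is assigned the linkage group of its
#' markers (a scaffold whose markers split across groups becomes a
#' conflict record and is not placed). Linkage groups inherit the
#' chromosome name carried by the majority of their previously anchored
#' scaffolds; each chromosome's map direction is normalised to agree with
#' the prior scaffold order, so orientations are comparable with the
#' prior. Ranks come from median marker cM (ties broken by prior rank,
#' then scaffold id). The change list labels every scaffold
#' `newly_anchored`, `reoriented`, `rearranged` or `unchanged` relative
#' to the prior placement.
#'
#' @param map a `linkage_map`.
#' @param prior prior placement data.frame (`scaffold`, `chromosome`,
#'   `rank`, `orientation`; unplaced rows have `NA` chromosome).
#' @param evidence evidence label recorded on placements (e.g.
#'   `"map_crossA"`).
#' @return list with `placements` (scaffold, chromosome, rank,
#'   orientation, evidence, n_markers, cM_span, cM_mid), `changes`
#'   (scaffold, change, prior/new chromosome) and `conflicts`.
#' @export
anchor_scaffolds <- function(map, prior, evidence = "map") {
  stopifnot(inherits(map, "linkage_map"))
  geno <- attr(map, "geno")
  mk <- geno$markers[match(map$marker, geno$markers$marker), ]
  mid <- (mk$start + mk$end) / 2
  df <- data.frame(scaffold = map$scaffold, group = map$group, cM = map$cM,
                   bp = mid, stringsAsFactors = FALSE)

  # scaffold -> group, flagging splits
  sg <- tapply(df$group, df$scaffold, function(g) unique(g))
  split_s <- names(sg)[vapply(sg, length, integer(1)) > 1]
  conflicts <- NULL
  if (length(split_s) > 0) {
    conflicts <- data.frame(scaffold = split_s,
                            groups = vapply(sg[split_s], paste, character(1),
                                            collapse = ","),
                            reason = "markers split across linkage groups",
                            stringsAsFactors = FALSE)
    df <- df[!(df$scaffold %in% split_s), ]
  }

  # group -> chromosome name by majority vote of prior-anchored members
  prior_chr <- stats::setNames(prior$chromosome, prior$scaffold)
  grp_chr <- vapply(split(df$scaffold, df$group), function(s) {
    pc <- prior_chr[unique(s)]
    pc <- pc[!is.na(pc)]
    if (length(pc) == 0) return(NA_character_)
    names(sort(table(pc), decreasing = TRUE))[1]
  }, character(1))
  # groups without any prior-anchored scaffold keep their group id
  miss <- is.na(grp_chr)
  grp_chr[miss] <- names(grp_chr)[miss]

  # per-scaffold summaries
  agg <- do.call(rbind, lapply(split(df, df$scaffold), function(d) {
    data.frame(scaffold = d$scaffold[1], group = d$group[1],
               chromosome = grp_chr[[d$group[1]]],
               cM_mid = stats::median(d$cM),
               cM_span = max(d$cM) - min(d$cM), n_markers = nrow(d),
               orientation = orient_scaffold(d$bp, d$cM),
               stringsAsFactors = FALSE)
  }))

  # normalise each chromosome's map direction against the prior order
  prior_rank <- stats::setNames(prior$rank, prior$scaffold)
  for (cn in unique(agg$chromosome)) {
    i <- which(agg$chromosome == cn)
    pr <- prior_rank[agg$scaffold[i]]
    ok <- !is.na(pr) & !is.na(prior_chr[agg$scaffold[i]]) &
      prior_chr[agg$scaffold[i]] == cn
    if (sum(ok) >= 2 && length(unique(agg$cM_mid[i][ok])) >= 2) {
      rho <- stats::cor(agg$cM_mid[i][ok], pr[ok], method = "spearman")
      if (!is.na(rho) && rho < 0) {
        agg$cM_mid[i] <- -agg$cM_mid[i]
        agg$orientation[i] <- c(`+` = "-", `-` = "+",
                                unknown = "unknown")[agg$orientation[i]]
      }
    }
  }

  # ranks by cM, ties by prior rank then scaffold id
  agg <- agg[order(agg$chromosome, agg$cM_mid,
                   prior_rank[agg$scaffold], agg$scaffold), ]
  agg$rank <- stats::ave(seq_len(nrow(agg)), agg$chromosome,
                         FUN = seq_along)
  placements <- data.frame(scaffold = agg$scaffold,
                           chromosome = agg$chromosome,
                           rank = as.integer(agg$rank),
                           orientation = agg$orientation,
                           evidence = evidence,
                           n_markers = agg$n_markers,
                           cM_span = agg$cM_span, cM_mid = agg$cM_mid,
                           stringsAsFactors = FALSE)
  rownames(placements) <- NULL

  # change list vs prior
  changes <- lapply(seq_len(nrow(placements)), function(i) {
    s <- placements$scaffold[i]
    pc <- prior_chr[[s]]
    if (is.na(pc) || is.null(pc))
      return(data.frame(scaffold = s, change = "newly_anchored",
                        prior_chromosome = NA_character_,
                        new_chromosome = placements$chromosome[i],
                        stringsAsFactors = FALSE))
    if (pc != placements$chromosome[i])
      return(data.frame(scaffold = s, change = "rearranged",
                        prior_chromosome = pc,
                        new_chromosome = placements$chromosome[i],
                        stringsAsFactors = FALSE))
    NULL
  })
  changes <- do.call(rbind, changes)
  # within-chromosome moves: scaffolds outside the longest common order
  moved <- character(0)
  for (cn in unique(placements$chromosome)) {
    p <- placements[placements$chromosome == cn, ]
    pr <- prior_rank[p$scaffold]
    anch <- !is.na(pr) & !is.na(prior_chr[p$scaffold]) & prior_chr[p$scaffold] == cn
    p <- p[anch, ]
    if (nrow(p) < 2) next
    p <- p[order(p$rank), ]
    keep <- lis_members(prior_rank[p$scaffold])
    moved <- c(moved, p$scaffold[!keep])
  }
  if (length(moved) > 0)
    changes <- rbind(changes,
                     data.frame(scaffold = moved, change = "rearranged",
                                prior_chromosome = prior_chr[moved],
                                new_chromosome = prior_chr[moved],
                                stringsAsFactors = FALSE))
  # reorientations (excluding scaffolds already flagged)
  flagged <- if (is.null(changes)) character(0) else changes$scaffold
  prior_or <- stats::setNames(prior$orientation, prior$scaffold)
  for (i in seq_len(nrow(placements))) {
    s <- placements$scaffold[i]
    if (s %in% flagged) next
    po <- prior_or[[s]]
    if (is.null(po) || is.na(po) || po == "unknown") next
    no <- placements$orientation[i]
    if (no != "unknown" && no != po)
      changes <- rbind(changes,
                       data.frame(scaffold = s, change = "reoriented",
                                  prior_chromosome = prior_chr[[s]],
                                  new_chromosome = placements$chromosome[i],
                                  stringsAsFactors = FALSE))
  }
  if (is.null(changes))
    changes <- data.frame(scaffold = character(0), change = character(0),
                          prior_chromosome = character(0),
                          new_chromosome = character(0),
                          stringsAsFactors = FALSE)
  rownames(changes) <- NULL
  list(placements = placements, changes = changes, conflicts = conflicts)
}

#' Merge two crosses' placements into a consensus scaffold map
#'
#' Scaffolds placed concordantly in both crosses enter the consensus with
#' cross-averaged position; scaffolds placed in only one cross are
#' accepted with single-cross evidence; a chromosome conflict between the
#' crosses leaves the scaffold unplaced and reported.
#'
#' @param pA,pB placement data.frames from [anchor_scaffolds()] (same
#'   prior), with `cM_mid` position columns.
#' @param evidA,evidB evidence labels for single-cross placements.
#' @return list `placements` (with `evidence` in consensus/`evidA`/
#'   `evidB`) and `conflicts`.
#' @export
consensus_map <- function(pA, pB, evidA = "map_crossA", evidB = "map_crossB") {
  all_s <- union(pA$scaffold, pB$scaffold)
  ia <- match(all_s, pA$scaffold); ib <- match(all_s, pB$scaffold)
  rows <- list(); confl <- list()
  for (k in seq_along(all_s)) {
    s <- all_s[k]
    a <- if (!is.na(ia[k])) pA[ia[k], ] else NULL
    b <- if (!is.na(ib[k])) pB[ib[k], ] else NULL
    if (!is.null(a) && !is.null(b)) {
      if (a$chromosome != b$chromosome) {
        confl[[length(confl) + 1]] <-
          data.frame(scaffold = s, chromA = a$chromosome, chromB = b$chromosome,
                     stringsAsFactors = FALSE)
        next
      }
      orient <- if (a$orientation == b$orientation) a$orientation
      else if (a$orientation == "unknown") b$orientation
      else if (b$orientation == "unknown") a$orientation
      else "unknown"
      rows[[length(rows) + 1]] <-
        data.frame(scaffold = s, chromosome = a$chromosome,
                   pos = mean(c(a$cM_mid, b$cM_mid)), orientation = orient,
                   evidence = "consensus",
                   n_markers = a$n_markers + b$n_markers,
                   stringsAsFactors = FALSE)
    } else {
      p <- if (!is.null(a)) a else b
      rows[[length(rows) + 1]] <-
        data.frame(scaffold = s, chromosome = p$chromosome, pos = p$cM_mid,
                   orientation = p$orientation,
                   evidence = if (!is.null(a)) evidA else evidB,
                   n_markers = p$n_markers, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$pos, out$scaffold), ]
  out$rank <- as.integer(stats::ave(seq_len(nrow(out)), out$chromosome,
                                    FUN = seq_along))
  rownames(out) <- NULL
  list(placements = out[, c("scaffold", "chromosome", "rank", "orientation",
                            "evidence", "n_markers")],
       conflicts = if (length(confl) > 0) do.call(rbind, confl) else NULL)
}

#' Place unanchored bins by read-count correlation
#'
#' For every unplaced bin, the Pearson correlation (across F2s) between
#' its genotype dosage and every placed marker's dosage is computed; the
#' bin is assigned the cM position of the best-correlated marker when the
#' correlation reaches `min_cor` and exceeds the best marker on any other
#' chromosome by `margin`. More sensitive than map-based anchoring for
#' small scaffolds with too little data for confident genotype calls.
#'
#' @param unplaced_dosage numeric matrix (bins x F2s) of freshwater
#'   dosages (0..1 scale; see [genotype_dosage()]).
#' @param placed_dosage numeric matrix (markers x F2s) for mapped markers.
#' @param marker_map data.frame with `marker`, `group` (or `chromosome`)
#'   and `cM` for the placed markers (rows matching `placed_dosage`).
#' @param min_cor,margin assignment thresholds.
#' @return data.frame per bin: `bin`, `best_marker`, `cor`, `chromosome`,
#'   `cM`, `placed` (logical).
#' @export
correlate_unplaced <- function(unplaced_dosage, placed_dosage, marker_map,
                               min_cor = 0.5, margin = 0.1) {
  if (is.null(dim(unplaced_dosage)))
    unplaced_dosage <- matrix(unplaced_dosage, nrow = 1)
  chrom <- if ("chromosome" %in% names(marker_map)) marker_map$chromosome
  else marker_map$group
  cc <- suppressWarnings(
    stats::cor(t(unplaced_dosage), t(placed_dosage),
               use = "pairwise.complete.obs"))
  out <- lapply(seq_len(nrow(unplaced_dosage)), function(i) {
    ci <- cc[i, ]
    if (all(is.na(ci)))
      return(data.frame(bin = i, best_marker = NA_character_, cor = NA_real_,
                        chromosome = NA_character_, cM = NA_real_,
                        placed = FALSE, stringsAsFactors = FALSE))
    best <- which.max(ci)
    other <- chrom != chrom[best]
    runner <- if (any(other)) max(ci[other], na.rm = TRUE) else -Inf
    placed <- !is.na(ci[best]) && ci[best] >= min_cor &&
      (ci[best] - runner) >= margin
    data.frame(bin = i,
               best_marker = marker_map$marker[best], cor = ci[best],
               chromosome = if (placed) chrom[best] else NA_character_,
               cM = if (placed) marker_map$cM[best] else NA_real_,
               placed = placed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(rownames(unplaced_dosage))) out$bin <- rownames(unplaced_dosage)
  out
}

#' Build a liftover table from a placement
#'
#' Maps original (scaffold, bp) coordinates onto the revised chromosome
#' sequence implied by a placement table, with fixed `gap_bp` N-gaps
#' between consecutive scaffolds (matching [write_agp()]), strand-aware.
#'
#' @param placements placement data.frame (`scaffold`, `chromosome`,
#'   `rank`, `orientation`).
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param gap_bp inter-scaffold gap.
#' @return data.frame of class `liftover_table`: one segment per placed
#'   scaffold with original and revised spans and strand.
#' @export
build_liftover <- function(placements, scaffold_lengths, gap_bp = 1000) {
  segs <- list()
  for (cn in unique(placements$chromosome[!is.na(placements$chromosome)])) {
    p <- placements[!is.na(placements$chromosome) & placements$chromosome == cn, ]
    p <- p[order(p$rank), ]
    pos <- 0
    for (i in seq_len(nrow(p))) {
      L <- scaffold_lengths[[p$scaffold[i]]]
      segs[[length(segs) + 1]] <-
        data.frame(scaffold = p$scaffold[i], s_start = 1, s_end = L,
                   strand = if (p$orientation[i] == "-") "-" else "+",
                   chromosome = cn, c_start = pos + 1, c_end = pos + L,
                   stringsAsFactors = FALSE)
      pos <- pos + L + gap_bp
    }
  }
  out <- do.call(rbind, segs)
  class(out) <- c("liftover_table", "data.frame")
  out
}

#' Lift coordinates between original and revised assemblies
#'
#' Strand-aware affine mapping through a [build_liftover()] table;
#' `liftover()` maps (scaffold, bp) to (chromosome, bp) and
#' `liftover_inverse()` maps back. Round-trips are exact. Positions on
#' unplaced scaffolds (or chromosome positions falling in gaps) return
#' `NA` with `mapped = FALSE`.
#'
#' @param scaffold,pos original coordinates (vectorised).
#' @param table a `liftover_table`.
#' @return data.frame `chromosome`, `pos`, `mapped`.
#' @export
liftover <- function(scaffold, pos, table) {
  i <- match(scaffold, table$scaffold)
  ok <- !is.na(i) & pos >= 1 & pos <= table$s_end[i]
  chrom <- ifelse(ok, table$chromosome[i], NA_character_)
  newp <- ifelse(ok,
                 ifelse(table$strand[i] == "-",
                        table$c_start[i] + (table$s_end[i] - pos),
                        table$c_start[i] + (pos - 1)),
                 NA_real_)
  data.frame(chromosome = chrom, pos = newp, mapped = ok)
}

#' @rdname liftover
#' @param chromosome,cpos revised coordinates (vectorised).
#' @return for `liftover_inverse()`: data.frame `scaffold`, `pos`,
#'   `mapped`.
#' @export
liftover_inverse <- function(chromosome, cpos, table) {
  n <- length(chromosome)
  scf <- rep(NA_character_, n); p <- rep(NA_real_, n); ok <- rep(FALSE, n)
  for (k in seq_len(n)) {
    i <- which(table$chromosome == chromosome[k] &
                 table$c_start <= cpos[k] & table$c_end >= cpos[k])
    if (length(i) == 1) {
      ok[k] <- TRUE
      scf[k] <- table$scaffold[i]
      p[k] <- if (table$strand[i] == "-") table$s_end[i] - (cpos[k] - table$c_start[i])
      else cpos[k] - table$c_start[i] + 1
    }
  }
  data.frame(scaffold = scf, pos = p, mapped = ok)
}
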