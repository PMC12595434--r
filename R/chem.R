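#' Parse compound structures from a SMILES or SDF file
#'
#' SMILES files hold one record per line (\code{SMILES [id]},
#' whitespace separated); SDF files are V2000. Records that fail
#' structure parsing or valence checking are skipped and reported, not
#' fatal — unless nothing at all parses.
#'
#' @param path Input file; format from the extension (\code{.smi},
#'   \code{.smiles}, \code{.txt} = SMILES; \code{.sdf}, \code{.mol} =
#'   SDF) unless \code{format} is given.
#' @param format \code{"smiles"} or \code{"sdf"}, optional.
#' @return A \code{compound_set}: list with \code{sdf} (an
#'   \code{SDFset}), \code{table} (data.frame id, smiles) and
#'   \code{skipped} (data.frame record, reason).
#' @export
parse_structures <- function(path, format = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "smiles"
  }
  format <- match.arg(format, c("smiles", "sdf"))
  if (format == "smiles") {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no SMILES records in ", path, call. = FALSE)
    parts <- strsplit(lines, "[ \t]+")
    smis <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2]
      else sprintf("CMPD%04d", i)
    }, "")
    compound_set_from_smiles(smis, ids)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    skipped <- data.frame(record = which(!valid),
                          reason = rep("invalid SDF record", sum(!valid)),
                          stringsAsFactors = FALSE)
    sdf <- sdf[valid]
    if (length(sdf) == 0) stop("no valid SDF records in ", path,
                               call. = FALSE)
    ids <- ChemmineR::sdfid(sdf)
    ids[!nzchar(ids)] <- sprintf("CMPD%04d", which(!nzchar(ids)))
    ChemmineR::cid(sdf) <- make.unique(ids)
    smis <- tryCatch(
      as.character(ChemmineR::sdf2smiles(sdf)),
      error = function(e) rep(NA_character_, length(sdf)))
    structure(list(sdf = sdf,
                   table = data.frame(id = ChemmineR::cid(sdf),
                                      smiles = smis,
                                      stringsAsFactors = FALSE),
                   skipped = skipped),
              class = "compound_set")
  }
}

#' Build a compound set directly from SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional ids (defaults to \code{CMPD0001}, ...).
#' @return A \code{compound_set}; unparseable strings are listed in
#'   \code{$skipped}.
#' @export
compound_set_from_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("CMPD%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  bad <- vapply(smiles, function(s)
    is.null(tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                     error = function(e) NULL)),
    TRUE, USE.NAMES = FALSE)
  if (all(bad)) stop("no valid SMILES records", call. = FALSE)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[!bad], ids[!bad]))
  ChemmineR::cid(sdf) <- ids[!bad]
  structure(list(sdf = sdf,
                 table = data.frame(id = ids[!bad],
                                    smiles = smiles[!bad],
                                    stringsAsFactors = FALSE),
                 skipped = data.frame(record = which(bad),
                                      reason = rep("unparseable SMILES",
                                                   sum(bad)),
                                      stringsAsFactors = FALSE)),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat("<compound_set> ", nrow(x$table), " compounds (",
      nrow(x$skipped), " skipped)\n", sep = "")
  print(utils::head(x$table), ...)
  invisible(x)
}

#' Compute physicochemical descriptors
#'
#' Adds molecular weight (average atomic masses, implicit hydrogens
#' included), cLogP (atomic-contribution method), Lipinski hydrogen
#' bond donor and acceptor counts, and topological polar surface area
#' (Ertl fragment contributions) to the compound table. All values
#' are computed from the parsed structures via OpenBabel.
#'
#' @param compounds A \code{compound_set}.
#' @return The \code{compound_set} with table columns mw, clogp, hbd,
#'   hba, tpsa added.
#' @export
compute_descriptors <- function(compounds) {
  stopifnot(inherits(compounds, "compound_set"))
  p <- ChemmineR::propOB(compounds$sdf)
  compounds$table$mw <- p$MW
  compounds$table$clogp <- p$logP
  compounds$table$hbd <- p$HBD
  compounds$table$hba <- p$HBA1
  compounds$table$tpsa <- p$TPSA
  compounds
}

#' A descriptor acceptance window
#'
#' @param lower,upper Bounds (may be infinite).
#' @param lower_closed,upper_closed Whether each bound is inclusive.
#' @return List of class \code{pc_window}.
#' @export
pc_window <- function(lower = -Inf, upper = Inf,
                      lower_closed = TRUE, upper_closed = TRUE) {
  stopifnot(lower <= upper)
  structure(list(lower = lower, upper = upper,
                 lower_closed = lower_closed,
                 upper_closed = upper_closed),
            class = "pc_window")
}

in_window <- function(x, w) {
  lo <- if (w$lower_closed) x >= w$lower else x > w$lower
  hi <- if (w$upper_closed) x <= w$upper else x < w$upper
  lo & hi
}

#' Drug-likeness windows of the virtual screening funnel
#'
#' MW < 450, cLogP in \verb{[1, 3]}, H-bond acceptors 1-5, donors 1-3,
#' TPSA < 140 square Angstrom. Each window can be overridden.
#'
#' @param mw,clogp,hbd,hba,tpsa \code{\link{pc_window}} objects.
#' @return Named list of windows.
#' @export
vhts_windows <- function(mw = pc_window(upper = 450, upper_closed = FALSE),
                         clogp = pc_window(1, 3),
                         hbd = pc_window(1, 3),
                         hba = pc_window(1, 5),
                         tpsa = pc_window(upper = 140,
                                          upper_closed = FALSE)) {
  list(mw = mw, clogp = clogp, hbd = hbd, hba = hba, tpsa = tpsa)
}

#' Apply physicochemical windows to a compound table
#'
#' @param compounds A \code{compound_set} with descriptors computed,
#'   or a data.frame with the descriptor columns.
#' @param windows Named list of \code{\link{pc_window}}s keyed by
#'   descriptor column (default \code{\link{vhts_windows}()}).
#' @return List with \code{pass} (data.frame of passing rows) and
#'   \code{fail} (failing rows plus a \code{reasons} column naming
#'   every violated descriptor).
#' @export
apply_physchem_filter <- function(compounds, windows = vhts_windows()) {
  tab <- if (inherits(compounds, "compound_set")) compounds$table
         else compounds
  miss <- setdiff(names(windows), names(tab))
  if (length(miss)) {
    stop("descriptor column(s) not present: ",
         paste(miss, collapse = ", "),
         "; run compute_descriptors() first", call. = FALSE)
  }
  viol <- sapply(names(windows), function(d)
    !in_window(tab[[d]], windows[[d]]))
  viol <- matrix(viol, nrow = nrow(tab),
                 dimnames = list(NULL, names(windows)))
  ok <- rowSums(viol) == 0
  fail <- tab[!ok, , drop = FALSE]
  fail$reasons <- apply(viol[!ok, , drop = FALSE], 1, function(v)
    paste(names(v)[v], collapse = ","))
  list(pass = tab[ok, , drop = FALSE], fail = fail)
}

#' Combine two docking ranks
#'
#' The combined score of a compound is the better (minimum) of its two
#' docking ranks, so a compound highly ranked by either scorer stays
#' competitive. Compounds missing either rank are excluded and
#' reported.
#'
#' @param ranks data.frame with columns id, hybrid_rank, moe_rank.
#' @return List with \code{ranked} (data.frame sorted by
#'   combined_rank, ties broken by hybrid_rank then id) and
#'   \code{excluded} (rows lacking a rank).
#' @export
combine_ranks <- function(ranks) {
  stopifnot(all(c("id", "hybrid_rank", "moe_rank") %in% names(ranks)))
  ok <- !is.na(ranks$hybrid_rank) & !is.na(ranks$moe_rank)
  excluded <- ranks[!ok, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "missing rank"
  r <- ranks[ok, , drop = FALSE]
  if (any(r$hybrid_rank < 1 | r$moe_rank < 1)) {
    stop("ranks must be positive integers", call. = FALSE)
  }
  r$combined_rank <- pmin(r$hybrid_rank, r$moe_rank)
  r <- r[order(r$combined_rank, r$hybrid_rank, r$id), , drop = FALSE]
  rownames(r) <- NULL
  list(ranked = r, excluded = excluded)
}

## ---- circular (Morgan/ECFP-style) fingerprints ----------------------

## deterministic 31-bit polynomial hash of a nonnegative integer vector
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x + 1)) %% 2147483647
  h
}

mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
              `6` = -2, `7` = -3)[as.character(chg_code)]
  charge[is.na(charge)] <- 0
  n <- nrow(ab)
  adj <- vector("list", n)
  ord <- vector("list", n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]; b <- bb[k, 2]; o <- bb[k, 3]
      adj[[a]] <- c(adj[[a]], b); ord[[a]] <- c(ord[[a]], o)
      adj[[b]] <- c(adj[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  list(elem = elem, charge = unname(charge), adj = adj, ord = ord,
       n = n, bonds = bb)
}

ring_atoms <- function(g) {
  ## an atom is in a ring iff one of its bonds lies on a cycle:
  ## removing the bond leaves its endpoints connected
  in_ring <- rep(FALSE, g$n)
  if (is.null(g$bonds) || nrow(g$bonds) == 0) return(in_ring)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
    if (in_ring[a] && in_ring[b]) next
    ## BFS from a to b avoiding this bond
    seen <- rep(FALSE, g$n); seen[a] <- TRUE
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (idx in seq_along(g$adj[[cur]])) {
        nb <- g$adj[[cur]][idx]
        if (cur == a && nb == b) next
        if (cur == b && nb == a) next
        if (!seen[nb]) {
          if (nb == b) { found <- TRUE; break }
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    if (found) { in_ring[a] <- TRUE; in_ring[b] <- TRUE }
  }
  in_ring
}

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                   P = 15, S = 16, Cl = 17, Se = 34, Br = 35, I = 53)
STD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                 P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

implicit_h <- function(g) {
  bsum <- vapply(seq_len(g$n), function(i) sum(g$ord[[i]]), 0)
  val <- STD_VALENCE[g$elem]
  val[is.na(val)] <- 0
  pmax(0, val + g$charge - bsum)
}

#' Circular topological fingerprint of one molecule
#'
#' Morgan-style circular fingerprint: each atom starts from an
#' invariant built from its element, heavy-atom degree, implicit
#' hydrogen count, formal charge and ring membership; over
#' \code{radius} rounds the invariant is re-hashed together with the
#' sorted (bond order, neighbor invariant) list, so each identifier
#' encodes the substructure within that bond radius. Radius 2
#' corresponds to ECFP4. Identifiers are folded into \code{nbits}
#' bits. The construction depends only on the molecular graph, never
#' on atom numbering.
#'
#' @param sdf A single \code{SDF} object (e.g. \code{cs$sdf[[i]]}).
#' @param radius Neighborhood radius in bonds (default 2).
#' @param nbits Folded length (default 2048).
#' @return Sorted integer vector of set bit positions (0-based), with
#'   attribute \code{nbits}.
#' @export
circular_fingerprint <- function(sdf, radius = 2, nbits = 2048) {
  g <- mol_graph(sdf)
  heavy <- g$elem != "H"
  inring <- ring_atoms(g)
  nh <- implicit_h(g)
  deg <- vapply(seq_len(g$n), function(i)
    sum(g$elem[g$adj[[i]]] != "H"), 0)
  anum <- ATOMIC_NUMBER[g$elem]
  anum[is.na(anum)] <- 0
  ids <- vapply(seq_len(g$n), function(i)
    hash_ints(c(anum[i], deg[i], nh[i], g$charge[i] + 8,
                as.integer(inring[i]))), 0)
  feats <- ids[heavy]
  if (radius > 0 && any(heavy)) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (i in which(heavy)) {
        nbs <- g$adj[[i]]
        os <- g$ord[[i]]
        keep <- g$elem[nbs] != "H"
        nbs <- nbs[keep]; os <- os[keep]
        if (!length(nbs)) next
        o2 <- order(os, ids[nbs])
        pairs <- as.vector(rbind(os[o2], ids[nbs][o2]))
        new_ids[i] <- hash_ints(c(r, ids[i], pairs))
      }
      ids <- new_ids
      feats <- c(feats, ids[heavy])
    }
  }
  bits <- sort(unique(feats %% nbits))
  structure(as.integer(bits), nbits = as.integer(nbits))
}

#' Fingerprints for every compound in a set
#'
#' @param compounds A \code{compound_set}.
#' @inheritParams circular_fingerprint
#' @return Named list of fingerprints (see
#'   \code{\link{circular_fingerprint}}).
#' @export
ecfp_fingerprints <- function(compounds, radius = 2, nbits = 2048) {
  stopifnot(inherits(compounds, "compound_set"))
  fps <- lapply(seq_len(length(compounds$sdf)), function(i)
    circular_fingerprint(compounds$sdf[[i]], radius, nbits))
  stats::setNames(fps, ChemmineR::cid(compounds$sdf))
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' \code{|A intersect B| / |A union B|}; defined as 1 when both sets
#' are empty.
#'
#' @param fp_a,fp_b Fingerprints from
#'   \code{\link{circular_fingerprint}} (integer bit positions with an
#'   \code{nbits} attribute).
#' @return Similarity in \verb{[0, 1]}.
#' @export
tanimoto <- function(fp_a, fp_b) {
  na <- attr(fp_a, "nbits")
  nb <- attr(fp_b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprint lengths differ (", na, " vs ", nb, ")",
         call. = FALSE)
  }
  if (length(fp_a) == 0 && length(fp_b) == 0) return(1)
  i <- length(intersect(fp_a, fp_b))
  i / (length(fp_a) + length(fp_b) - i)
}

#' Greedy diversity selection by sphere exclusion
#'
#' Walks the compound list in its given (rank) order and keeps a
#' compound only if its Tanimoto similarity to every previously kept
#' compound is below \code{sim_cutoff}. Because the list is ranked
#' best-first, the kept set retains the best-scored representative of
#' each structural cluster. With \code{as_distance = TRUE} the cutoff
#' is a Tanimoto \emph{distance} floor instead (keep when
#' \code{1 - sim > sim_cutoff}).
#'
#' @param ids Character vector of compound ids in ranked order.
#' @param fingerprints Named list covering all \code{ids}.
#' @param sim_cutoff Similarity ceiling between kept compounds
#'   (default 0.52).
#' @param max_picks Stop after keeping this many (default unlimited).
#' @param as_distance Interpret the cutoff as a distance floor.
#' @return Character vector of kept ids (a subsequence of
#'   \code{ids}).
#' @export
diversity_pick <- function(ids, fingerprints, sim_cutoff = 0.52,
                           max_picks = Inf, as_distance = FALSE) {
  stopifnot(all(ids %in% names(fingerprints)))
  kept <- character(0)
  kept_fp <- list()
  for (id in ids) {
    if (length(kept) >= max_picks) break
    fp <- fingerprints[[id]]
    ok <- TRUE
    for (kf in kept_fp) {
      s <- tanimoto(fp, kf)
      redundant <- if (as_distance) (1 - s) <= sim_cutoff
                   else s >= sim_cutoff
      if (redundant) { ok <- FALSE; break }
    }
    if (ok) {
      kept <- c(kept, id)
      kept_fp[[length(kept_fp) + 1L]] <- fp
    }
  }
  kept
}

#' Read a docking-rank CSV
#' @param path CSV with header id, hybrid_rank, moe_rank.
#' @return data.frame with those columns.
#' @export
read_rank_csv <- function(path) {
  if (!file.exists(path)) stop("rank file not found: ", path,
                               call. = FALSE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "hybrid_rank", "moe_rank")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("rank file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  r
}
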