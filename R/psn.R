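# Persistence-filtered protein structure network (PSN).
#
# Per-frame geometric detection of salt bridges (SB), hydrogen bonds (HB)
# and hydrophobic contacts (HC); persistence = fraction of production-run
# frames in which a contact's geometric criteria hold; a per-class
# persistence threshold chosen by the largest-hydrophobic-cluster
# criterion; the merged residue graph with node degrees; hub and
# delta-degree analysis; and inter-domain interaction tables.
#
# Two detection modes are supported.  "all_atom" applies class-specific
# distance (and, for HB when hydrogens exist, angle) constraints on the
# chemically relevant atoms.  "residue_center" applies a per-class cutoff to
# representative-point distances (C-alpha if present, else the residue
# centroid) and is suitable for coarse-grained models.

CHARGED_POS <- c("LYS", "ARG")
CHARGED_NEG <- c("ASP", "GLU")
HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
POLAR_HB <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "LYS", "ARG",
              "ASP", "GLU", "CYS", "TRP")

SB_GROUP_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

HB_DONOR_ATOMS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  TRP = "NE1", CYS = "SG"
)
HB_ACCEPTOR_ATOMS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parameters for protein structure network detection
#'
#' @param mode `"residue_center"` or `"all_atom"`.
#' @param cutoffs named numeric vector of class cutoffs in Angstrom;
#'   defaults `c(SB = 4.5, HB = 3.5, HC = 5.0)`.  In all-atom mode these are
#'   the charged-group minimum distance (SB), the donor-acceptor heavy-atom
#'   distance (HB) and the side-chain-centre distance (HC); in
#'   residue-center mode they bound the representative-point distance.
#' @param hb_angle_min minimum donor-H...acceptor angle in degrees when
#'   hydrogens are present (default 120).
#' @param seq_exclusion minimum sequence separation `|i - j|` for a pair to
#'   count (default 2, i.e. adjacent residues are excluded).
#' @param his_charged treat histidine as protonatable-positive for salt
#'   bridges (default `TRUE`).
#' @return a list of class `mdh_psn_params`.
#' @export
psn_params <- function(mode = c("residue_center", "all_atom"),
                       cutoffs = c(SB = 4.5, HB = 3.5, HC = 5.0),
                       hb_angle_min = 120, seq_exclusion = 2L,
                       his_charged = TRUE) {
  mode <- match.arg(mode)
  if (!all(c("SB", "HB", "HC") %in% names(cutoffs)))
    abort_config("cutoffs must name SB, HB and HC")
  structure(list(mode = mode, cutoffs = cutoffs, hb_angle_min = hb_angle_min,
                 seq_exclusion = as.integer(seq_exclusion),
                 his_charged = isTRUE(his_charged)),
            class = "mdh_psn_params")
}

# representative point per residue: CA if present, else centroid
residue_points <- function(atoms, coords) {
  key <- paste(atoms$chain, atoms$resno)
  resk <- unique(key)
  pts <- matrix(NA_real_, length(resk), 3L)
  resno <- integer(length(resk))
  resid <- character(length(resk))
  for (i in seq_along(resk)) {
    sel <- which(key == resk[i])
    ca <- sel[atoms$elety[sel] == "CA"]
    use <- if (length(ca)) ca[1] else sel
    pts[i, ] <- colMeans(coords[use, , drop = FALSE])
    resno[i] <- atoms$resno[sel[1]]
    resid[i] <- atoms$resid[sel[1]]
  }
  list(resno = resno, resid = resid, pts = pts)
}

# pairs (i < j by resno) from a logical eligibility on residues a x b
eligible_pairs <- function(resno, ok_a, ok_b, seq_exclusion) {
  ia <- which(ok_a)
  ib <- which(ok_b)
  if (!length(ia) || !length(ib)) return(matrix(integer(0), ncol = 2L))
  g <- expand.grid(i = ia, j = ib)
  g <- g[abs(resno[g$i] - resno[g$j]) >= seq_exclusion & resno[g$i] < resno[g$j], ,
         drop = FALSE]
  unique(as.matrix(g))
}

detect_residue_center <- function(atoms, coords, class, params) {
  rp <- residue_points(atoms, coords)
  pos_set <- if (params$his_charged) c(CHARGED_POS, "HIS") else CHARGED_POS
  elig <- switch(class,
    SB = {
      pos <- rp$resid %in% pos_set
      neg <- rp$resid %in% CHARGED_NEG
      rbind(eligible_pairs(rp$resno, pos, neg, params$seq_exclusion),
            eligible_pairs(rp$resno, neg, pos, params$seq_exclusion))
    },
    HB = {
      pol <- rp$resid %in% POLAR_HB
      eligible_pairs(rp$resno, pol, pol, params$seq_exclusion)
    },
    HC = {
      hp <- rp$resid %in% HYDROPHOBIC
      eligible_pairs(rp$resno, hp, hp, params$seq_exclusion)
    })
  elig <- unique(elig)
  if (!nrow(elig)) return(data.frame(residue_a = integer(0), residue_b = integer(0)))
  d <- sqrt(rowSums((rp$pts[elig[, 1], , drop = FALSE] -
                     rp$pts[elig[, 2], , drop = FALSE])^2))
  hit <- d <= params$cutoffs[[class]]
  data.frame(residue_a = rp$resno[elig[hit, 1]], residue_b = rp$resno[elig[hit, 2]])
}

# minimum distance between two atom coordinate sets
min_dist <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(Inf)
  min(sqrt(outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)))
}

group_coords <- function(atoms, coords, sel, names) {
  coords[sel[atoms$elety[sel] %in% names], , drop = FALSE]
}

detect_all_atom <- function(atoms, coords, class, params) {
  key <- paste(atoms$chain, atoms$resno)
  resk <- unique(key)
  sel_by_res <- split(seq_len(nrow(atoms)), factor(key, levels = resk))
  resno <- vapply(sel_by_res, function(s) atoms$resno[s[1]], integer(1))
  resid <- vapply(sel_by_res, function(s) atoms$resid[s[1]], character(1))
  has_h <- any(atoms$element == "H" | grepl("^H", atoms$elety))
  nres <- length(resk)
  pos_set <- if (params$his_charged) c(CHARGED_POS, "HIS") else CHARGED_POS
  cut <- params$cutoffs[[class]]

  hit_pair <- function(i, j) {
    si <- sel_by_res[[i]]; sj <- sel_by_res[[j]]
    ri <- resid[i]; rj <- resid[j]
    if (class == "SB") {
      ok <- (ri %in% pos_set && rj %in% CHARGED_NEG) ||
            (ri %in% CHARGED_NEG && rj %in% pos_set)
      if (!ok) return(FALSE)
      gi <- group_coords(atoms, coords, si, SB_GROUP_ATOMS[[ri]])
      gj <- group_coords(atoms, coords, sj, SB_GROUP_ATOMS[[rj]])
      return(min_dist(gi, gj) <= cut)
    }
    if (class == "HC") {
      if (!(ri %in% HYDROPHOBIC && rj %in% HYDROPHOBIC)) return(FALSE)
      sci <- coords[si[!(atoms$elety[si] %in% BACKBONE_ATOMS) &
                       atoms$element[si] != "H"], , drop = FALSE]
      scj <- coords[sj[!(atoms$elety[sj] %in% BACKBONE_ATOMS) &
                       atoms$element[sj] != "H"], , drop = FALSE]
      if (!nrow(sci) || !nrow(scj)) return(FALSE)
      return(sqrt(sum((colMeans(sci) - colMeans(scj))^2)) <= cut)
    }
    # HB: donor(heavy) of one residue within cutoff of acceptor of the other
    don_at <- function(s, r) c(HB_DONOR_ATOMS$backbone, HB_DONOR_ATOMS[[r]])
    acc_at <- function(s, r) c(HB_ACCEPTOR_ATOMS$backbone, HB_ACCEPTOR_ATOMS[[r]])
    check_da <- function(sd_, rd, sa_, ra) {
      dons <- sd_[atoms$elety[sd_] %in% don_at(sd_, rd)]
      accs <- sa_[atoms$elety[sa_] %in% acc_at(sa_, ra)]
      for (d in dons) for (a in accs) {
        dd <- sqrt(sum((coords[d, ] - coords[a, ])^2))
        if (dd > cut) next
        if (!has_h) return(TRUE)
        hs <- sd_[grepl("^H", atoms$elety[sd_])]
        if (!length(hs)) return(TRUE)
        hd <- sqrt(rowSums(sweep(coords[hs, , drop = FALSE], 2L, coords[d, ])^2))
        hb <- hs[hd <= 1.2]
        if (!length(hb)) return(TRUE)
        for (h in hb) {
          v1 <- coords[d, ] - coords[h, ]
          v2 <- coords[a, ] - coords[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          if (ang >= params$hb_angle_min) return(TRUE)
        }
      }
      FALSE
    }
    check_da(si, ri, sj, rj) || check_da(sj, rj, si, ri)
  }

  out_a <- integer(0); out_b <- integer(0)
  for (i in seq_len(nres - 1L)) for (j in (i + 1L):nres) {
    if (abs(resno[i] - resno[j]) < params$seq_exclusion) next
    if (hit_pair(i, j)) {
      a <- min(resno[i], resno[j]); b <- max(resno[i], resno[j])
      out_a <- c(out_a, a); out_b <- c(out_b, b)
    }
  }
  data.frame(residue_a = out_a, residue_b = out_b)
}

#' Detect non-covalent interactions in one frame
#'
#' @param frame an `mdh_structure` (or `mdh_traj`, first frame).
#' @param class interaction class: `"SB"` (salt bridge), `"HB"` (hydrogen
#'   bond) or `"HC"` (hydrophobic contact).
#' @param params an [psn_params()].
#' @return data frame with columns `residue_a < residue_b` (file numbering).
#' @export
detect_interactions <- function(frame, class, params = psn_params()) {
  if (!class %in% c("SB", "HB", "HC"))
    abort_config(sprintf("unknown interaction class '%s'", class))
  atoms <- frame$atoms
  coords <- coords_of(frame)
  if (params$mode == "all_atom") {
    if (all(atoms$elety == "CA"))
      abort_config("all-atom detection requested on a C-alpha-only model; use residue_center mode")
    detect_all_atom(atoms, coords, class, params)
  } else {
    detect_residue_center(atoms, coords, class, params)
  }
}

#' Interaction persistence over the production run
#'
#' Persistence of a residue pair is the fraction of production-run frames in
#' which its geometric criteria are fulfilled (an exact ratio of frame
#' counts).  Pairs never detected are absent from the output.
#'
#' @param traj an `mdh_traj`.
#' @param class interaction class (`"SB"`, `"HB"`, `"HC"`).
#' @param params an [psn_params()].
#' @param production_start first production frame (default 1).
#' @param offset numbering offset subtracted from file residue numbers so
#'   records are reported in sequence numbering (default 0).
#' @return data frame with columns `residue_a`, `residue_b`, `class`,
#'   `persistence`, sorted by decreasing persistence.
#' @export
interaction_persistence <- function(traj, class, params = psn_params(),
                                    production_start = 1L, offset = 0L) {
  nf <- n_frames(traj)
  if (production_start < 1L || production_start > nf)
    abort_param("production_start outside the trajectory")
  frames <- production_start:nf
  counts <- new.env(parent = emptyenv())
  for (f in frames) {
    hits <- detect_interactions(traj_frame(traj, f), class, params)
    if (nrow(hits)) {
      keys <- paste(hits$residue_a, hits$residue_b)
      for (k in keys) assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L, counts)
    }
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(residue_a = integer(0), residue_b = integer(0),
                      class = character(0), persistence = numeric(0)))
  ab <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  out <- data.frame(residue_a = ab[, 1] - offset, residue_b = ab[, 2] - offset,
                    class = class,
                    persistence = vapply(keys, get, numeric(1), envir = counts) /
                      length(frames))
  out <- out[order(-out$persistence, out$residue_a, out$residue_b), ]
  rownames(out) <- NULL
  out
}

# largest connected component size of a persistence-filtered graph
largest_cluster <- function(records, p) {
  nodes <- sort(unique(c(records$residue_a, records$residue_b)))
  keep <- records$persistence >= p
  if (!length(nodes)) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(records$residue_a[keep]),
               to = as.character(records$residue_b[keep])),
    directed = FALSE, vertices = as.character(nodes))
  as.integer(max(igraph::components(g)$csize))
}

#' Persistence threshold by the largest-hydrophobic-cluster criterion
#'
#' Scans thresholds `p` from 0 to 1 in steps; at each `p` the hydrophobic
#' graph keeps edges with `persistence >= p`, and the size of its largest
#' connected component is recorded.  The critical persistence is the `p` at
#' the largest single-step drop of that size (ties resolved to the smallest
#' such `p`); if the size never drops within the scan, the final step
#' boundary (1.0) is returned.
#'
#' @param hc_records hydrophobic-contact records from
#'   [interaction_persistence()].
#' @param step scan step (default 0.02).
#' @return `p_crit`, with attributes `thresholds` and `cluster_sizes` (the
#'   full scan curve).
#' @export
persistence_threshold <- function(hc_records, step = 0.02) {
  if (is.null(hc_records) || nrow(hc_records) == 0L)
    abort_config("no hydrophobic-contact records: supply an explicit p_crit")
  ps <- seq(0, 1, by = step)
  sizes <- vapply(ps, function(p) largest_cluster(hc_records, p), integer(1))
  drops <- c(0L, sizes[-length(sizes)] - sizes[-1])
  p_crit <- if (max(drops) > 0L) ps[which.max(drops)] else ps[length(ps)]
  attr(p_crit, "thresholds") <- ps
  attr(p_crit, "cluster_sizes") <- sizes
  p_crit
}

#' Build the merged protein structure network
#'
#' Filters each interaction class by its persistence threshold
#' (`persistence >= p_crit[class]`) and merges the class graphs into one
#' residue network.  By default the node degree counts distinct interacting
#' partners (a pair linked by both SB and HB contributes one to each node's
#' degree); set `per_class_degree = TRUE` to count each class edge
#' separately.
#'
#' @param records data frame of interaction records (columns `residue_a`,
#'   `residue_b`, `class`, `persistence`), e.g. `rbind()` of
#'   [interaction_persistence()] outputs.
#' @param p_crit named numeric vector of per-class thresholds in \[0, 1\]
#'   (classes missing from the vector default to 0.5).
#' @param nodes optional integer vector of residues to include as nodes even
#'   if isolated (e.g. all residues of the protein).
#' @param per_class_degree logical; see above.
#' @return object of class `mdh_psn`: list with `edges` (filtered records),
#'   `graph` (igraph, one edge per distinct pair), `degree` (named integer)
#'   and `nodes`.
#' @export
build_psn <- function(records, p_crit, nodes = NULL, per_class_degree = FALSE) {
  if (any(p_crit < 0 | p_crit > 1)) abort_param("p_crit must lie in [0, 1]")
  thr <- function(cl) if (cl %in% names(p_crit)) p_crit[[cl]] else 0.5
  keep <- records$persistence >= vapply(records$class, thr, numeric(1))
  edges <- records[keep, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("residue_a", "residue_b", "class")]), ,
                 drop = FALSE]
  all_nodes <- sort(unique(c(nodes, edges$residue_a, edges$residue_b)))
  pair_edges <- unique(edges[, c("residue_a", "residue_b")])
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pair_edges$residue_a),
               to = as.character(pair_edges$residue_b)),
    directed = FALSE, vertices = as.character(all_nodes))
  deg <- if (per_class_degree) {
    d <- setNames(integer(length(all_nodes)), as.character(all_nodes))
    tab <- table(c(edges$residue_a, edges$residue_b))
    d[names(tab)] <- as.integer(tab)
    d
  } else igraph::degree(g)
  rownames(edges) <- NULL
  structure(list(edges = edges, graph = g,
                 degree = setNames(as.integer(deg), names(deg)),
                 nodes = all_nodes),
            class = "mdh_psn")
}

#' @export
print.mdh_psn <- function(x, ...) {
  cat(sprintf("<mdh_psn> %d nodes, %d class edges (%d distinct pairs), max degree %d\n",
              length(x$nodes), nrow(x$edges),
              igraph::ecount(x$graph), max(c(0L, x$degree))))
  invisible(x)
}

psn_degree_of <- function(psn, residues) {
  d <- setNames(integer(length(residues)), as.character(residues))
  known <- intersect(names(psn$degree), names(d))
  d[known] <- psn$degree[known]
  d
}

#' Identify network hubs across systems
#'
#' A residue is a hub if its connectivity degree is *strictly* greater than
#' `k_min` in at least one of the supplied systems.
#'
#' @param graphs named list of [build_psn()] results, one per system.
#' @param k_min degree threshold (hubs have `k > k_min`).
#' @return data frame with one row per hub: `residue`, one degree column per
#'   system (`degree.<system>`), and `max_degree`.
#' @export
find_hubs <- function(graphs, k_min = 6L) {
  if (!length(graphs)) abort_config("no graphs supplied")
  if (k_min < 1L) abort_param("k_min must be >= 1")
  residues <- sort(unique(unlist(lapply(graphs, `[[`, "nodes"))))
  degmat <- vapply(graphs, psn_degree_of, integer(length(residues)),
                   residues = residues)
  degmat <- matrix(degmat, nrow = length(residues),
                   dimnames = list(NULL, names(graphs)))
  is_hub <- apply(degmat, 1L, function(k) any(k > k_min))
  out <- data.frame(residue = residues[is_hub])
  for (s in names(graphs)) out[[paste0("degree.", s)]] <- degmat[is_hub, s]
  out$max_degree <- if (any(is_hub)) apply(degmat[is_hub, , drop = FALSE], 1L, max)
                    else integer(0)
  out
}

#' Per-residue degree change between open and closed networks
#'
#' `delta_degree(i) = k_open(i) - k_closed(i)`; a residue absent from a
#' graph has degree 0 there.
#'
#' @param open_graph,closed_graph [build_psn()] results.
#' @param residues residues to report (default: union of both node sets).
#' @return data frame with `residue`, `k_open`, `k_closed`, `delta_degree`.
#' @export
delta_degree <- function(open_graph, closed_graph, residues = NULL) {
  if (is.null(residues))
    residues <- sort(unique(c(open_graph$nodes, closed_graph$nodes)))
  ko <- psn_degree_of(open_graph, residues)
  kc <- psn_degree_of(closed_graph, residues)
  data.frame(residue = residues, k_open = as.integer(ko),
             k_closed = as.integer(kc),
             delta_degree = as.integer(ko - kc))
}

#' Inter-domain interaction table
#'
#' Lists the persistent non-covalent interactions between residues of two
#' disjoint domains, keeping only records whose persistence exceeds the
#' class threshold, sorted by decreasing persistence.
#'
#' @param records interaction records (sequence numbering), as for
#'   [build_psn()].
#' @param p_crit named per-class thresholds.
#' @param domains an [domain_set()].
#' @param a,b domain names (must not overlap).
#' @return data frame `residue_a` (in domain `a`), `residue_b` (in domain
#'   `b`), `class`, `persistence`.
#' @export
interdomain_table <- function(records, p_crit, domains, a, b) {
  ra <- domain_residues(domains, a)
  rb <- domain_residues(domains, b)
  if (length(intersect(ra, rb))) abort_config("domains overlap")
  thr <- function(cl) if (cl %in% names(p_crit)) p_crit[[cl]] else 0.5
  keep <- records$persistence > vapply(records$class, thr, numeric(1))
  rec <- records[keep, , drop = FALSE]
  fwd <- rec$residue_a %in% ra & rec$residue_b %in% rb
  rev <- rec$residue_a %in% rb & rec$residue_b %in% ra
  out <- rbind(
    rec[fwd, c("residue_a", "residue_b", "class", "persistence")],
    if (any(rev)) data.frame(residue_a = rec$residue_b[rev],
                             residue_b = rec$residue_a[rev],
                             class = rec$class[rev],
                             persistence = rec$persistence[rev])
  )
  out <- out[order(-out$persistence, out$residue_a, out$residue_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a PSN as GraphML
#'
#' @param psn a [build_psn()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psn_graphml <- function(psn, path) {
  igraph::write_graph(psn$graph, path, format = "graphml")
  invisible(path)
}
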