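## Steric clash detection (van der Waals overlap of heavy atoms) and greedy
## side-chain relief by chi-dihedral grid search. Neighbor search uses a
## spatial grid (cell lists), never all-pairs, so large assemblies stay
## tractable.

## Bondi-style heavy-atom van der Waals radii by element (angstroms).
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  if (anyNA(r)) {
    miss <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(miss, collapse = ", "))
  }
  unname(r)
}

## All atom pairs with distance <= cutoff, by cell-list grid.
## Returns data.table(i, j, d) with i < j.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  dt <- data.table::data.table(
    i = seq_len(n),
    cx = as.integer(floor(xyz[, 1] / cutoff)),
    cy = as.integer(floor(xyz[, 2] / cutoff)),
    cz = as.integer(floor(xyz[, 3] / cutoff)))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx >= 0), ]
  res <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    b <- data.table::data.table(
      j = dt$i, cx = dt$cx + offs$dx[k], cy = dt$cy + offs$dy[k],
      cz = dt$cz + offs$dz[k])
    m <- merge(dt, b, by = c("cx", "cy", "cz"), allow.cartesian = TRUE)
    if (offs$dx[k] == 0 && offs$dy[k] == 0 && offs$dz[k] == 0) {
      m <- m[m$i < m$j, ]
    }
    res[[k]] <- m[, c("i", "j")]
  }
  pr <- data.table::rbindlist(res)
  if (nrow(pr) == 0) return(data.table::data.table(i = integer(0),
                                                   j = integer(0),
                                                   d = numeric(0)))
  ii <- pmin(pr$i, pr$j); jj <- pmax(pr$i, pr$j)
  pr <- data.table::data.table(i = ii, j = jj)
  pr <- unique(pr)
  d <- sqrt(rowSums((xyz[pr$i, , drop = FALSE] -
                       xyz[pr$j, , drop = FALSE])^2))
  pr$d <- d
  pr[pr$d <= cutoff, ]
}

## Excluded intra-residue pairs (bond-graph distance <= 3, i.e. bonded, 1-3
## and 1-4 neighbors, whose separations are fixed or near-fixed by covalent
## geometry), cached per residue type as "A|B" keys with A < B.
.exclusion_cache <- new.env(parent = emptyenv())

residue_exclusions <- function(resname) {
  if (!is.null(.exclusion_cache[[resname]])) return(.exclusion_cache[[resname]])
  bonds <- residue_bonds(resname)
  nbr <- list()
  for (b in bonds) {
    nbr[[b[1]]] <- union(nbr[[b[1]]], b[2])
    nbr[[b[2]]] <- union(nbr[[b[2]]], b[1])
  }
  keys <- character(0)
  for (a in names(nbr)) {
    one <- nbr[[a]]
    two <- unique(unlist(nbr[one]))
    three <- unique(unlist(nbr[two]))
    for (b in setdiff(unique(c(one, two, three)), a))
      keys <- c(keys, paste(sort(c(a, b)), collapse = "|"))
  }
  out <- unique(keys)
  .exclusion_cache[[resname]] <- out
  out
}

## Backbone-link exclusions across adjacent residues (graph distance <= 3
## through the C(i)-N(i+1) bond); "p" atoms from the carbonyl-side residue,
## "q" from the amide side. Proline adds its ring CD next to N.
LINK_EXCLUSIONS <- c("C N", "CA N", "O N", "C CA", "CB N", "O CA",
                     "CA CA", "C C", "C CB", "N N")
LINK_EXCLUSIONS_PRO <- c(LINK_EXCLUSIONS, "C CD", "O CD", "CA CD")

## TRUE for pairs that must not be scored: bonded/1-3 within a residue and
## backbone links across adjacent residues.
excluded_pair <- function(at, i, j) {
  same_res <- at$chain[i] == at$chain[j] & at$resno[i] == at$resno[j] &
    at$insert[i] == at$insert[j]
  out <- logical(length(i))
  if (any(same_res)) {
    key <- paste(pmin(at$elety[i[same_res]], at$elety[j[same_res]]),
                 pmax(at$elety[i[same_res]], at$elety[j[same_res]]),
                 sep = "|")
    resn <- at$resid[i[same_res]]
    out[same_res] <- mapply(function(k, rn) k %in% residue_exclusions(rn),
                            key, resn)
  }
  adj <- at$chain[i] == at$chain[j] & at$insert[i] == at$insert[j] &
    abs(at$resno[i] - at$resno[j]) == 1 & !same_res
  if (any(adj)) {
    ii <- i[adj]; jj <- j[adj]
    ## orient: "p" = lower resno (carbonyl side), "q" = upper (amide side)
    swap <- at$resno[ii] > at$resno[jj]
    p <- ifelse(swap, jj, ii); q <- ifelse(swap, ii, jj)
    link <- paste(at$elety[p], at$elety[q])
    pro_q <- at$resid[q] == "PRO"
    out[adj] <- ifelse(pro_q, link %in% LINK_EXCLUSIONS_PRO,
                       link %in% LINK_EXCLUSIONS)
  }
  out
}

#' Detect steric clashes
#'
#' All heavy-atom pairs whose van der Waals overlap (`r_i + r_j - d`)
#' exceeds a threshold. Pairs whose separation is fixed by covalent
#' geometry are not scored: bonded, 1-3 and 1-4 neighbours within a
#' residue, and the same neighbourhood across the backbone link between
#' adjacent residues.
#'
#' @param x a `dd_assembly` or `dd_structure`.
#' @param overlap_threshold minimum overlap to report (default 0.4 A).
#' @return data.frame of clash records: `chain_i`, `resno_i`, `resid_i`,
#'   `elety_i`, same for `j`, `distance`, `overlap`; sorted by decreasing
#'   overlap.
#' @export
detect_clashes <- function(x, overlap_threshold = 0.4) {
  s <- if (inherits(x, "dd_assembly")) assembly_structure(x) else x
  s <- heavy_atoms(s)
  at <- s$atoms
  xyz <- structure_xyz(s)
  rmax <- max(vdw_radius(unique(at$element)))
  pr <- neighbor_pairs(xyz, 2 * rmax - overlap_threshold)
  if (nrow(pr) == 0) return(empty_clash_table())
  ri <- vdw_radius(at$element[pr$i]); rj <- vdw_radius(at$element[pr$j])
  ov <- ri + rj - pr$d
  keep <- ov > overlap_threshold
  pr <- pr[keep, ]; ov <- ov[keep]
  if (nrow(pr) == 0) return(empty_clash_table())
  excl <- excluded_pair(at, pr$i, pr$j)
  pr <- pr[!excl, ]; ov <- ov[!excl]
  if (nrow(pr) == 0) return(empty_clash_table())
  out <- data.frame(
    chain_i = at$chain[pr$i], resno_i = at$resno[pr$i],
    resid_i = at$resid[pr$i], elety_i = at$elety[pr$i],
    chain_j = at$chain[pr$j], resno_j = at$resno[pr$j],
    resid_j = at$resid[pr$j], elety_j = at$elety[pr$j],
    distance = pr$d, overlap = ov, stringsAsFactors = FALSE)
  out[order(-out$overlap), ]
}

empty_clash_table <- function() {
  data.frame(chain_i = character(0), resno_i = integer(0),
             resid_i = character(0), elety_i = character(0),
             chain_j = character(0), resno_j = integer(0),
             resid_j = character(0), elety_j = character(0),
             distance = numeric(0), overlap = numeric(0))
}

## Total overlap of a clash table.
total_overlap <- function(clashes) if (nrow(clashes) == 0) 0 else sum(clashes$overlap)

#' Relieve clashes by greedy side-chain rotation
#'
#' Greedy per-residue chi-dihedral grid search (30-degree steps), worst
#' clashing rotatable residue first, accepting only moves that strictly
#' reduce the total overlap. The backbone never moves; glycine, alanine
#' and proline side chains are not rotated. Terminates at zero clashes,
#' when no move improves, or at `max_iters` accepted moves.
#'
#' @param x a `dd_assembly` or `dd_structure`.
#' @param max_iters maximum accepted moves (default 100).
#' @param overlap_threshold clash threshold (default 0.4 A).
#' @param seed recorded in the report; the algorithm is deterministic
#'   (ties broken by chain/residue order).
#' @return list with `relieved` (same type as `x`), `report` (list:
#'   `initial_overlap`, `final_overlap`, `overlap_trace`, `n_moves`,
#'   `converged`, `seed`).
#' @export
relieve <- function(x, max_iters = 100, overlap_threshold = 0.4, seed = 1L) {
  is_assembly <- inherits(x, "dd_assembly")
  s <- if (is_assembly) assembly_structure(x) else x
  at <- s$atoms
  heavy <- at$element != "H"
  xyz <- as.matrix(at[, c("x", "y", "z")])
  clashes <- detect_clashes(set_structure_xyz(s, xyz), overlap_threshold)
  trace <- numeric(0)
  tot <- total_overlap(clashes)
  init <- tot
  n_moves <- 0L
  blocked <- character(0)   # residues that could not improve at current state
  while (tot > 0 && n_moves < max_iters) {
    ## rank rotatable residues by their clash involvement
    key_i <- paste(clashes$chain_i, clashes$resno_i)
    key_j <- paste(clashes$chain_j, clashes$resno_j)
    inv <- tapply(c(clashes$overlap, clashes$overlap), c(key_i, key_j), sum)
    resid_of <- function(k) {
      parts <- strsplit(k, " ")[[1]]
      at$resid[at$chain == parts[1] & at$resno == as.integer(parts[2])][1]
    }
    cand <- names(sort(inv, decreasing = TRUE))
    cand <- cand[vapply(cand, function(k) resid_of(k) %in% names(CHI_ATOMS),
                        TRUE)]
    cand <- setdiff(cand, blocked)
    if (length(cand) == 0) break
    improved <- FALSE
    for (k in cand) {
      parts <- strsplit(k, " ")[[1]]
      ch <- parts[1]; rn <- as.integer(parts[2])
      resn <- at$resid[at$chain == ch & at$resno == rn][1]
      move <- try_rotamer(at, xyz, heavy, ch, rn, resn, tot,
                          overlap_threshold)
      if (!is.null(move)) {
        xyz <- move$xyz
        tot <- move$total
        clashes <- detect_clashes(set_structure_xyz(s, xyz),
                                  overlap_threshold)
        tot <- total_overlap(clashes)
        n_moves <- n_moves + 1L
        trace <- c(trace, tot)
        blocked <- character(0)
        improved <- TRUE
        break
      } else {
        blocked <- c(blocked, k)
      }
    }
    if (!improved) break
  }
  s_out <- set_structure_xyz(s, xyz)
  out <- if (is_assembly) {
    subs <- lapply(x$subunits, function(sub) {
      rows <- s_out$atoms$chain == sub$chain
      sub$structure$atoms[, c("x", "y", "z")] <-
        s_out$atoms[rows, c("x", "y", "z")]
      sub
    })
    new_assembly(subs, generator = x$generator)
  } else s_out
  list(relieved = out,
       report = list(initial_overlap = init, final_overlap = tot,
                     overlap_trace = trace, n_moves = n_moves,
                     converged = tot == 0, seed = seed))
}

## Try all chi grid rotations for one residue; return the best strictly
## improving coordinates or NULL.
try_rotamer <- function(at, xyz, heavy, ch, rn, resn, current_total,
                        overlap_threshold) {
  chis <- CHI_ATOMS[[resn]]
  if (is.null(chis)) return(NULL)
  res_rows <- which(at$chain == ch & at$resno == rn)
  ## local neighborhood for scoring: atoms within 14 A of the residue CB
  cb <- xyz[res_rows[match("CB", at$elety[res_rows])], ]
  near <- which(heavy & sqrt(rowSums(sweep(xyz, 2, cb)^2)) < 14)
  best_xyz <- NULL
  best_total <- current_total
  xyz_try <- xyz
  for (ci in seq_along(chis)) {
    quad <- chis[[ci]]
    moving_names <- chi_moving_atoms(resn, ci)
    mrows <- res_rows[at$elety[res_rows] %in% moving_names]
    if (length(mrows) == 0) next
    b <- xyz_try[res_rows[match(quad[2], at$elety[res_rows])], ]
    c_ <- xyz_try[res_rows[match(quad[3], at$elety[res_rows])], ]
    if (anyNA(b) || anyNA(c_)) next
    base <- xyz_try[mrows, , drop = FALSE]
    score0 <- local_overlap(at, xyz_try, mrows, near, overlap_threshold)
    best_delta <- 0
    best_rot <- NULL
    for (ang in seq(30, 330, by = 30)) {
      R <- rotation_about_axis(c_ - b, ang)
      rot <- sweep(sweep(base, 2, c_) %*% t(R), 2, c_, `+`)
      xyz_try[mrows, ] <- rot
      sc <- local_overlap(at, xyz_try, mrows, near, overlap_threshold)
      if (sc - score0 < best_delta - 1e-12) {
        best_delta <- sc - score0
        best_rot <- rot
      }
    }
    xyz_try[mrows, ] <- if (is.null(best_rot)) base else best_rot
  }
  new_total_local <- local_overlap(at, xyz_try, res_rows,
                                   which(heavy), overlap_threshold)
  old_total_local <- local_overlap(at, xyz, res_rows,
                                   which(heavy), overlap_threshold)
  if (new_total_local < old_total_local - 1e-9)
    return(list(xyz = xyz_try, total = current_total -
                  (old_total_local - new_total_local)))
  NULL
}

## Sum of overlaps between `rows` and `near` atoms (excluding non-scored
## pairs), given coordinates.
local_overlap <- function(at, xyz, rows, near, overlap_threshold) {
  near <- setdiff(near, rows)
  if (length(near) == 0 || length(rows) == 0) return(0)
  a <- xyz[rows, , drop = FALSE]; b <- xyz[near, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  rsum <- outer(vdw_radius(at$element[rows]), vdw_radius(at$element[near]), `+`)
  ov <- rsum - sqrt(d2)
  hit <- which(ov > overlap_threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0)
  ii <- rows[hit[, 1]]; jj <- near[hit[, 2]]
  excl <- excluded_pair(at, ii, jj)
  sum(ov[hit][!excl])
}
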