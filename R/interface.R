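## Inter-subunit interface analysis: residue contact maps with helix-index
## offsets, face/offset statistics for the three canonical DD interaction
## surfaces, interface-type classification, and a simplified pairwise
## potential (screened Coulomb with distance-dependent dielectric + 12-6
## Lennard-Jones) decomposed per residue with lowest-four averaging across
## subunit copies.

#' Canonical DD interaction face definitions (query numbering)
#'
#' The three surfaces of the query death domain: type Ia pivoted by Lys60
#' (acidic partner Asp33 on the neighbouring subunit), type IIa pivoted by
#' Trp74 (surrounded by Phe18, Asp19, Leu20, Pro21, Gln78), type IIb
#' pivoted by Arg97 with Tyr105 (partner Asp19 on the subunit four below).
#' Trp52, Arg56 and Gln64 are auxiliary interactive residues.
#'
#' @return named list of face definitions (`label`, `pivots`, `partners`,
#'   `surround`).
#' @export
dd_faces <- function() {
  list(
    Ia = list(label = "Ia", pivots = 60, partners = 33, surround = integer(0)),
    IIa = list(label = "IIa", pivots = 74, partners = integer(0),
               surround = c(18, 19, 20, 21, 78)),
    IIb = list(label = "IIb", pivots = c(97, 105), partners = 19,
               surround = integer(0)),
    aux = list(label = "aux", pivots = c(52, 56, 64), partners = integer(0),
               surround = integer(0))
  )
}

## chain -> helix index lookup for an assembly's merged structure
chain_index_map <- function(a) {
  tab <- assembly_table(a)
  stats::setNames(tab$helix_index, tab$chain)
}

#' Inter-subunit residue contact map
#'
#' All residue pairs from different subunits whose minimum heavy-atom
#' distance is within the cutoff, stored canonically (lower helix index
#' first) with the subunit-index offset.
#'
#' @param a a `dd_assembly`.
#' @param cutoff heavy-atom distance cutoff in angstroms (default 4.5).
#' @return data.frame: `subunit_i`, `chain_i`, `resno_i`, `resid_i`, the
#'   same for `j`, `dist` (minimum heavy-atom distance), `offset`
#'   (`subunit_j - subunit_i`), `type` (interface class from
#'   [classify_interface()]).
#' @export
contact_map <- function(a, cutoff = 4.5) {
  s <- heavy_atoms(assembly_structure(a))
  idx <- chain_index_map(a)
  at <- s$atoms
  pr <- neighbor_pairs(structure_xyz(s), cutoff)
  pr <- pr[at$chain[pr$i] != at$chain[pr$j], ]
  if (nrow(pr) == 0) return(empty_contact_table())
  ## canonical order by helix index
  ni <- unname(idx[at$chain[pr$i]]); nj <- unname(idx[at$chain[pr$j]])
  swap <- ni > nj
  tmp <- pr$i[swap]; pr$i[swap] <- pr$j[swap]; pr$j[swap] <- tmp
  ni2 <- pmin(ni, nj); nj2 <- pmax(ni, nj)
  dt <- data.table::data.table(
    subunit_i = ni2, chain_i = at$chain[pr$i], resno_i = at$resno[pr$i],
    resid_i = at$resid[pr$i],
    subunit_j = nj2, chain_j = at$chain[pr$j], resno_j = at$resno[pr$j],
    resid_j = at$resid[pr$j], d = pr$d)
  dist <- NULL; d <- NULL  # appease R CMD check
  res <- dt[, list(dist = min(d)),
            by = c("subunit_i", "chain_i", "resno_i", "resid_i",
                   "subunit_j", "chain_j", "resno_j", "resid_j")]
  res <- as.data.frame(res)
  res$offset <- res$subunit_j - res$subunit_i
  res$type <- classify_interface(-res$offset)
  res[order(res$subunit_i, res$subunit_j, res$resno_i, res$resno_j), ]
}

empty_contact_table <- function() {
  data.frame(subunit_i = integer(0), chain_i = character(0),
             resno_i = integer(0), resid_i = character(0),
             subunit_j = integer(0), chain_j = character(0),
             resno_j = integer(0), resid_j = character(0),
             dist = numeric(0), offset = integer(0), type = character(0))
}

#' Classify a subunit-offset as a DD interface type
#'
#' `dn` is the offset of the partner relative to the pivot subunit
#' (`n_partner - n_pivot`). Offsets of magnitude 1 are type I, 3 or 4 type
#' II; the `a` face looks up the helix (negative `dn`), the `b` face down
#' (positive `dn`). Anything else is "unclassified".
#'
#' @param dn integer vector of partner offsets.
#' @return character vector: "Ia", "Ib", "IIa", "IIb" or "unclassified".
#' @export
classify_interface <- function(dn) {
  out <- rep("unclassified", length(dn))
  out[dn == -1] <- "Ia"
  out[dn == 1] <- "Ib"
  out[dn %in% c(-3, -4)] <- "IIa"
  out[dn %in% c(3, 4)] <- "IIb"
  out
}

#' Partner-offset statistics for a face's pivot residues
#'
#' For every pivot residue of the face and every query subunit, reports
#' the offsets of all contacting partner subunits (within the cutoff) and,
#' separately, the offset of the nearest partner subunit by minimum
#' heavy-atom distance regardless of the cutoff.
#'
#' @param a a `dd_assembly`.
#' @param face one face definition from [dd_faces()].
#' @param cutoff contact cutoff (default 4.5 A).
#' @param partner_resno optional: restrict the "nearest" search to this
#'   residue on partner subunits (e.g. 19 to ask which subunit's Asp19 is
#'   closest to the pivot).
#' @return data.frame: `face`, `pivot_resno`, `subunit` (helix index of
#'   the pivot copy), `partner_subunit`, `offset`, `dist`, `kind`
#'   ("contact" or "nearest").
#' @export
face_offsets <- function(a, face, cutoff = 4.5, partner_resno = NULL) {
  s <- heavy_atoms(assembly_structure(a))
  idx <- chain_index_map(a)
  at <- s$atoms
  xyz <- structure_xyz(s)
  tab <- assembly_table(a)
  qtab <- tab[tab$layer == "QUERY", , drop = FALSE]
  if (nrow(qtab) == 0) stop("assembly has no query subunits")
  avail <- unique(at$resno[at$chain %in% qtab$chain])
  missing_p <- setdiff(face$pivots, avail)
  if (length(missing_p))
    stop("pivot residue(s) ", paste(missing_p, collapse = ", "),
         " absent from the query model; available residue numbers span ",
         min(avail), "..", max(avail))
  rows <- list()
  for (p in face$pivots) {
    for (qi in seq_len(nrow(qtab))) {
      ch <- qtab$chain[qi]; n0 <- qtab$helix_index[qi]
      prow <- which(at$chain == ch & at$resno == p)
      if (length(prow) == 0) next
      pm <- xyz[prow, , drop = FALSE]
      other <- unique(at$chain[at$chain != ch])
      dmin <- vapply(other, function(oc) {
        orow <- which(at$chain == oc &
                        (if (is.null(partner_resno)) TRUE
                         else at$resno == partner_resno))
        if (length(orow) == 0) return(Inf)
        om <- xyz[orow, , drop = FALSE]
        d2 <- outer(rowSums(pm^2), rowSums(om^2), `+`) - 2 * pm %*% t(om)
        sqrt(max(0, min(d2)))
      }, 0)
      dmin <- dmin[is.finite(dmin)]
      if (length(dmin) == 0) next
      contacts <- names(dmin)[dmin <= cutoff]
      for (oc in contacts) {
        rows[[length(rows) + 1]] <- data.frame(
          face = face$label, pivot_resno = p, subunit = n0,
          partner_subunit = unname(idx[oc]),
          offset = unname(idx[oc]) - n0, dist = dmin[[oc]],
          kind = "contact", stringsAsFactors = FALSE)
      }
      nearest <- names(dmin)[which.min(dmin)]
      rows[[length(rows) + 1]] <- data.frame(
        face = face$label, pivot_resno = p, subunit = n0,
        partner_subunit = unname(idx[nearest]),
        offset = unname(idx[nearest]) - n0, dist = min(dmin),
        kind = "nearest", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(
    data.frame(face = character(0), pivot_resno = integer(0),
               subunit = integer(0), partner_subunit = integer(0),
               offset = integer(0), dist = numeric(0), kind = character(0)))
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Simplified pairwise potential

## 12-6 Lennard-Jones parameters per element: rmin (A, per atom; pair rmin
## is the sum) and well depth eps (kcal/mol).
LJ_PARAMS <- list(C = c(rmin = 1.908, eps = 0.086),
                  N = c(rmin = 1.824, eps = 0.170),
                  O = c(rmin = 1.661, eps = 0.210),
                  S = c(rmin = 2.000, eps = 0.250))

## Formal side-chain tip charges (elementary charges), backbone neutral.
TIP_CHARGES <- list(
  LYS = c(NZ = +1),
  ARG = c(NH1 = +0.5, NH2 = +0.5),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5))

#' Parameters of the simplified interface potential
#'
#' Screened Coulomb term `k q_i q_j / (eps(r) r)` with distance-dependent
#' dielectric `eps(r) = 4r`, plus a 12-6 Lennard-Jones term
#' `eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)`. Unit formal charges sit on
#' the basic/acidic side-chain tips; everything else is neutral. This is a
#' single-conformation surrogate score (arbitrary kcal/mol-scale units),
#' not a free energy.
#'
#' @param coulomb_k Coulomb constant (332.0636 kcal A / (mol e^2)).
#' @param cutoff pair-distance cutoff in angstroms (default 10).
#' @param lj named list of per-element `c(rmin, eps)`.
#' @param charges named list: residue -> named atom charges.
#' @return a `dd_potential` parameter object.
#' @export
potential_params <- function(coulomb_k = 332.0636, cutoff = 10,
                             lj = LJ_PARAMS, charges = TIP_CHARGES) {
  stopifnot(cutoff > 0)
  if (any(vapply(lj, function(p) p["eps"] <= 0, TRUE)))
    stop("Lennard-Jones well depths must be > 0")
  structure(list(coulomb_k = coulomb_k, cutoff = cutoff, lj = lj,
                 charges = charges),
            class = "dd_potential")
}

atom_charges <- function(at, params) {
  q <- numeric(nrow(at))
  for (rn in names(params$charges)) {
    tips <- params$charges[[rn]]
    for (an in names(tips)) {
      q[at$resid == rn & at$elety == an] <- tips[[an]]
    }
  }
  q
}

## Atom-pair energies between different subunits of a merged structure.
## Returns data.table with residue identities of both sides and energy terms.
pair_energy_table <- function(s, params) {
  s <- heavy_atoms(s)
  at <- s$atoms
  missing_el <- setdiff(unique(at$element), names(params$lj))
  if (length(missing_el))
    stop("no Lennard-Jones parameters for atom type(s): ",
         paste(missing_el, collapse = ", "))
  pr <- neighbor_pairs(structure_xyz(s), params$cutoff)
  pr <- pr[at$chain[pr$i] != at$chain[pr$j], ]
  if (nrow(pr) == 0)
    return(data.table::data.table(
      chain_i = character(0), resno_i = integer(0), resid_i = character(0),
      chain_j = character(0), resno_j = integer(0), resid_j = character(0),
      d = numeric(0), elec = numeric(0), lj = numeric(0), energy = numeric(0)))
  q <- atom_charges(at, params)
  elec <- params$coulomb_k * q[pr$i] * q[pr$j] / (4 * pr$d^2)
  rmin_i <- vapply(params$lj[at$element[pr$i]], `[[`, 0, "rmin")
  rmin_j <- vapply(params$lj[at$element[pr$j]], `[[`, 0, "rmin")
  eps <- sqrt(vapply(params$lj[at$element[pr$i]], `[[`, 0, "eps") *
                vapply(params$lj[at$element[pr$j]], `[[`, 0, "eps"))
  sr <- ((rmin_i + rmin_j) / pr$d)
  ljv <- eps * (sr^12 - 2 * sr^6)
  data.table::data.table(
    chain_i = at$chain[pr$i], resno_i = at$resno[pr$i],
    resid_i = at$resid[pr$i],
    chain_j = at$chain[pr$j], resno_j = at$resno[pr$j],
    resid_j = at$resid[pr$j],
    d = pr$d, elec = elec, lj = ljv, energy = elec + ljv)
}

#' Mean of the four lowest values
#'
#' The per-residue aggregation rule: across the per-copy energies of a
#' residue, average the four most favourable (lowest). With fewer than
#' four values, all are averaged.
#'
#' @param x numeric vector.
#' @return scalar mean of the lowest four (or all, if fewer).
#' @export
lowest_four_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(sort(x)[seq_len(min(4, length(x)))])
}

#' Per-residue decomposition of the inter-subunit interface energy
#'
#' For every residue of every query copy, sums the pairwise energies of
#' its inter-subunit atom pairs within the cutoff (the full pair energy is
#' credited to both residues of a pair). Per-residue values are then
#' aggregated across subunit copies by the lowest-four rule.
#'
#' @param a a `dd_assembly` (>= 2 subunits).
#' @param params a `dd_potential` (default [potential_params()]).
#' @param scope "query" (decompose query copies only, the default) or
#'   "all" (every subunit; useful for conservation checks).
#' @return object of class `dd_energy`: list with `per_copy` (data.frame:
#'   `resno`, `resid`, `chain`, `subunit`, `elec`, `lj`, `energy`),
#'   `aggregated` (data.frame: `resno`, `resid`, `energy`, `n_copies`,
#'   `flagged`), and `total_pair_energy` (sum over unique inter-subunit
#'   pairs).
#' @export
per_residue_energy <- function(a, params = potential_params(),
                               scope = c("query", "all")) {
  scope <- match.arg(scope)
  if (length(a$subunits) < 2) stop("need at least two subunits")
  pe <- pair_energy_table(assembly_structure(a), params)
  tab <- assembly_table(a)
  keep_chains <- if (scope == "query") tab$chain[tab$layer == "QUERY"]
  else tab$chain
  idx <- chain_index_map(a)
  both <- data.table::rbindlist(list(
    pe[, list(chain = pe$chain_i, resno = pe$resno_i, resid = pe$resid_i,
              elec = pe$elec, lj = pe$lj, energy = pe$energy)],
    pe[, list(chain = pe$chain_j, resno = pe$resno_j, resid = pe$resid_j,
              elec = pe$elec, lj = pe$lj, energy = pe$energy)]))
  both <- both[both$chain %in% keep_chains, ]
  per_copy <- if (nrow(both) == 0) {
    data.frame(chain = character(0), resno = integer(0), resid = character(0),
               elec = numeric(0), lj = numeric(0), energy = numeric(0))
  } else {
    as.data.frame(both[, list(elec = sum(elec), lj = sum(lj),
                              energy = sum(energy)),
                       by = c("chain", "resno", "resid")])
  }
  ## complete the grid: residues with no pairs have zero energy
  full <- do.call(rbind, lapply(keep_chains, function(ch) {
    sub <- Filter(function(s) s$chain == ch, a$subunits)[[1]]
    at <- sub$structure$atoms
    keys <- !duplicated(at$resno)
    data.frame(chain = ch, resno = at$resno[keys], resid = at$resid[keys],
               stringsAsFactors = FALSE)
  }))
  per_copy <- merge(full, per_copy, by = c("chain", "resno", "resid"),
                    all.x = TRUE)
  per_copy[is.na(per_copy)] <- 0
  per_copy$subunit <- unname(idx[per_copy$chain])
  per_copy <- per_copy[order(per_copy$resno, per_copy$subunit), ]
  energy <- NULL
  agg <- data.table::as.data.table(per_copy)[
    , list(energy = lowest_four_mean(energy), n_copies = .N),
    by = c("resno", "resid")]
  agg <- as.data.frame(agg)
  agg$flagged <- agg$n_copies < 4
  agg <- agg[order(agg$resno), ]
  structure(list(per_copy = per_copy, aggregated = agg,
                 total_pair_energy = sum(pe$energy), params = params,
                 scope = scope),
            class = "dd_energy")
}

#' @export
print.dd_energy <- function(x, ...) {
  cat("Per-residue interface energies:", nrow(x$aggregated),
      "residues x", length(unique(x$per_copy$chain)), "copies; total pair energy",
      format(x$total_pair_energy, digits = 6), "\n")
  invisible(x)
}

#' Rank residues by aggregated interface energy
#'
#' @param energies a `dd_energy` (or its `aggregated` data.frame).
#' @return the aggregated table ordered most-favourable (lowest) first;
#'   ties broken by residue number.
#' @export
rank_residues <- function(energies) {
  agg <- if (inherits(energies, "dd_energy")) energies$aggregated else energies
  agg[order(agg$energy, agg$resno), ]
}
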