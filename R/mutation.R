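## In-silico point mutations of the query panel and interface-score deltas.
## Mutations are applied to every query copy simultaneously (the biological
## mutant is homotypic); outputs are rank/sign-level scores, not calibrated
## free-energy differences.

#' The built-in mutation panel
#'
#' The point mutations studied for the query death domain: the three face
#' pivots (W74A, R97Q, K60E, Y105A), the IIa surround stretch (F18A, D19N,
#' L20A, P21A, P22A, A23S) and the configurable Q78 substitution.
#'
#' @param q78_to one-letter target for the Gln78 substitution (default "A").
#' @return data.frame: `label`, `resno`, `from`, `to`.
#' @export
mutation_panel <- function(q78_to = "A") {
  p <- data.frame(
    resno = c(74, 97, 60, 105, 18, 19, 20, 21, 22, 23, 78),
    from = c("W", "R", "K", "Y", "F", "D", "L", "P", "P", "A", "Q"),
    to = c("A", "Q", "E", "A", "A", "N", "A", "A", "A", "S", q78_to),
    stringsAsFactors = FALSE)
  p$label <- paste0(p$from, p$resno, p$to)
  p[, c("label", "resno", "from", "to")]
}

#' Specify a point mutation
#'
#' @param resno residue position (query numbering).
#' @param from expected one-letter residue at the position (checked
#'   against the model).
#' @param to one-letter replacement.
#' @return a `dd_mutation`.
#' @export
mutation_spec <- function(resno, from, to) {
  stopifnot(length(resno) == 1, nchar(from) == 1, nchar(to) == 1)
  structure(list(resno = as.integer(resno), from = toupper(from),
                 to = toupper(to),
                 label = paste0(toupper(from), resno, toupper(to))),
            class = "dd_mutation")
}

## Replace the side chain of one residue in a single-chain structure.
mutate_residue_atoms <- function(at, resno, to3) {
  rows <- which(at$resno == resno)
  if (length(rows) == 0) stop("residue ", resno, " not present")
  res <- at[rows, , drop = FALSE]
  getxyz <- function(nm) {
    k <- match(nm, res$elety)
    if (is.na(k)) return(NULL)
    as.numeric(res[k, c("x", "y", "z")])
  }
  N <- getxyz("N"); CA <- getxyz("CA"); C <- getxyz("C"); O <- getxyz("O")
  if (is.null(N) || is.null(CA) || is.null(C) || is.null(O))
    stop("residue ", resno, " lacks a complete backbone")
  new <- residue_atom_rows(at$chain[rows[1]], resno, to3, N, CA, C, O)
  new$insert <- res$insert[1]
  ## keep the template CB orientation when both have one
  if ("CB" %in% res$elety && "CB" %in% new$elety) {
    cb <- getxyz("CB")
    new[new$elety == "CB", c("x", "y", "z")] <- as.list(cb)
    sc <- build_sidechain(to3, list(N = N, CA = CA, CB = cb))
    if (!is.null(sc))
      new[match(rownames(sc), new$elety), c("x", "y", "z")] <-
        as.data.frame(sc)
  }
  rbind(at[seq_len(rows[1] - 1), , drop = FALSE], new,
        at[setdiff(seq_len(nrow(at)), c(seq_len(rows[1] - 1), rows)), ,
           drop = FALSE])
}

#' Apply a point mutation to every query copy of an assembly
#'
#' The side chain is replaced using the ideal-geometry threading rules
#' (backbone and CB untouched where present), in all query copies, then
#' the mutated residues are locally debumped by the chi grid search.
#'
#' @param a a `dd_assembly`.
#' @param m a `dd_mutation`.
#' @param debump relieve clashes at the mutated positions (default TRUE).
#' @param overlap_threshold clash threshold for the local relief.
#' @return the mutated `dd_assembly`.
#' @export
apply_mutation <- function(a, m, debump = TRUE, overlap_threshold = 0.4) {
  stopifnot(inherits(m, "dd_mutation"))
  to3 <- aa_one_to_three(m$to)
  qs_idx <- which(vapply(a$subunits, `[[`, "", "layer") == "QUERY")
  if (length(qs_idx) == 0) stop("assembly has no query subunits")
  for (k in qs_idx) {
    at <- a$subunits[[k]]$structure$atoms
    rows <- which(at$resno == m$resno)
    if (length(rows) == 0)
      stop("position ", m$resno, " missing from query copy ",
           a$subunits[[k]]$chain)
    cur <- aa_three_to_one(at$resid[rows[1]])
    if (!identical(cur, m$from))
      stop("from-residue mismatch at ", m$resno, ": model has ", cur,
           ", mutation expects ", m$from)
  }
  if (m$from == m$to) return(a)
  for (k in qs_idx) {
    at <- a$subunits[[k]]$structure$atoms
    a$subunits[[k]]$structure <- dd_structure(
      mutate_residue_atoms(at, m$resno, to3),
      title = a$subunits[[k]]$structure$title,
      source = paste0(a$subunits[[k]]$structure$source, " +", m$label))
    a$subunits[[k]]$provenance$mutation <- m$label
  }
  if (debump && to3 %in% names(CHI_ATOMS)) {
    s <- assembly_structure(a)
    at <- s$atoms
    xyz <- structure_xyz(s)
    heavy <- at$element != "H"
    qchains <- vapply(a$subunits[qs_idx], `[[`, "", "chain")
    tot0 <- Inf
    for (ch in qchains) {
      mv <- try_rotamer(at, xyz, heavy, ch, m$resno, to3, tot0,
                        overlap_threshold)
      if (!is.null(mv)) xyz <- mv$xyz
    }
    s <- set_structure_xyz(s, xyz)
    for (k in qs_idx) {
      rows <- s$atoms$chain == a$subunits[[k]]$chain
      a$subunits[[k]]$structure$atoms[, c("x", "y", "z")] <-
        s$atoms[rows, c("x", "y", "z")]
    }
  }
  a
}

#' Interface-score change of a mutation
#'
#' `dE = E_mut - E_wt` over inter-subunit atom pairs that involve the
#' mutated position on a query copy, grouped by interface class of the
#' partner offset (type I: |dn| = 1; type II: |dn| in {3, 4}; a-face when
#' the partner lies up the helix). Zero rows are kept so a position
#' without contacts reports dE = 0.
#'
#' @param wt wild-type `dd_assembly`.
#' @param mut mutated `dd_assembly` (same geometry, from
#'   [apply_mutation()]).
#' @param resno the mutated position.
#' @param params a `dd_potential`.
#' @return data.frame: `class`, `dE_elec`, `dE_lj`, `dE`, plus an "all"
#'   row.
#' @export
delta_score <- function(wt, mut, resno, params = potential_params()) {
  score <- function(a) {
    pe <- pair_energy_table(assembly_structure(a), params)
    tab <- assembly_table(a)
    idx <- chain_index_map(a)
    qchains <- tab$chain[tab$layer == "QUERY"]
    ## pairs where the mutated position on a query copy is residue i or j
    sel_i <- pe$chain_i %in% qchains & pe$resno_i == resno
    sel_j <- pe$chain_j %in% qchains & pe$resno_j == resno
    ## offset of the partner relative to the mutated residue's subunit
    dn <- c(unname(idx[pe$chain_j[sel_i]]) - unname(idx[pe$chain_i[sel_i]]),
            unname(idx[pe$chain_i[sel_j]]) - unname(idx[pe$chain_j[sel_j]]))
    el <- c(pe$elec[sel_i], pe$elec[sel_j])
    lj <- c(pe$lj[sel_i], pe$lj[sel_j])
    data.frame(class = classify_interface(dn), elec = el, lj = lj)
  }
  classes <- c("Ia", "Ib", "IIa", "IIb", "unclassified")
  sum_by <- function(df) {
    out <- data.frame(class = classes, elec = 0, lj = 0)
    if (nrow(df)) {
      agg <- stats::aggregate(cbind(elec, lj) ~ class, df, sum)
      k <- match(agg$class, out$class)
      out$elec[k] <- agg$elec; out$lj[k] <- agg$lj
    }
    out
  }
  w <- sum_by(score(wt)); m <- sum_by(score(mut))
  res <- data.frame(class = classes,
                    dE_elec = m$elec - w$elec,
                    dE_lj = m$lj - w$lj)
  res <- rbind(res, data.frame(class = "all",
                               dE_elec = sum(res$dE_elec),
                               dE_lj = sum(res$dE_lj)))
  res$dE <- res$dE_elec + res$dE_lj
  res
}

#' Scan a panel of mutations
#'
#' Applies each panel mutation to the assembly and reports the per-class
#' interface-score deltas.
#'
#' @param a wild-type `dd_assembly`.
#' @param panel data.frame as from [mutation_panel()].
#' @param params a `dd_potential`.
#' @param debump locally relieve mutated side chains (default TRUE).
#' @return data.frame: `label`, `class`, `dE_elec`, `dE_lj`, `dE`.
#' @export
mutation_scan <- function(a, panel = mutation_panel(),
                          params = potential_params(), debump = TRUE) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    m <- mutation_spec(panel$resno[i], panel$from[i], panel$to[i])
    mut <- apply_mutation(a, m, debump = debump)
    d <- delta_score(a, mut, m$resno, params)
    cbind(label = m$label, d)
  })
  do.call(rbind, out)
}
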