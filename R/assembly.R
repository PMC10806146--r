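## Assembly construction: threading a query DD sequence onto a template
## backbone, placing query copies on template subunits (the octamer
## extension), and re-anchoring the extended layer one step down the helix.
##
## An `dd_assembly` is an ordered list of placed subunits, each a
## single-chain structure tagged with a helix index, a layer label
## (template layers or "QUERY") and provenance.

new_assembly <- function(subunits, generator = NULL) {
  structure(list(subunits = subunits, generator = generator),
            class = "dd_assembly")
}

#' @export
print.dd_assembly <- function(x, ...) {
  layers <- vapply(x$subunits, `[[`, "", "layer")
  cat("dd_assembly:", length(x$subunits), "subunits (",
      paste(sprintf("%s:%d", names(table(layers)), table(layers)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Subunit bookkeeping table of an assembly
#'
#' @param a a `dd_assembly`.
#' @return data.frame with columns `chain` (output chain id), `layer`,
#'   `helix_index`, `local_index` (1..k within the layer), `rmsd`
#'   (placement rmsd, NA for template subunits).
#' @export
assembly_table <- function(a) {
  do.call(rbind, lapply(a$subunits, function(s) {
    data.frame(chain = s$chain, layer = s$layer, helix_index = s$helix_index,
               local_index = s$local_index,
               rmsd = if (is.null(s$provenance$rmsd)) NA_real_ else s$provenance$rmsd,
               stringsAsFactors = FALSE)
  }))
}

#' Merge an assembly into a single multi-chain structure
#'
#' @param a a `dd_assembly`.
#' @return a `dd_structure`; chain ids as in [assembly_table()].
#' @export
assembly_structure <- function(a) {
  at <- do.call(rbind, lapply(a$subunits, function(s) {
    x <- s$structure$atoms
    x$chain <- s$chain
    x
  }))
  dd_structure(at, title = "dd assembly",
               source = "assembly_structure()")
}

## subset helper
query_subunits <- function(a) Filter(function(s) s$layer == "QUERY", a$subunits)

#' Assemble subunits by hand
#'
#' Builds a `dd_assembly` from single-chain structures with explicit helix
#' indices and layer labels; useful for toys and custom analyses.
#'
#' @param structures list of single-chain `dd_structure`s.
#' @param helix_indices integer helix index per subunit.
#' @param layers layer label per subunit (default all "QUERY").
#' @param chains output chain ids (default A, B, C, ...).
#' @return a `dd_assembly`.
#' @export
manual_assembly <- function(structures, helix_indices,
                            layers = rep("QUERY", length(structures)),
                            chains = LETTERS[seq_along(structures)]) {
  stopifnot(length(structures) == length(helix_indices),
            length(structures) == length(layers))
  subunits <- lapply(seq_along(structures), function(i) {
    list(chain = chains[i], layer = layers[i],
         helix_index = as.integer(helix_indices[i]),
         local_index = i, structure = structures[[i]],
         provenance = list(note = "manual subunit"))
  })
  new_assembly(subunits)
}

#' Thread a query sequence onto a template chain backbone
#'
#' Builds a threading stand-in for an unavailable query-domain model:
#' at aligned positions with identical residues, all template atoms are
#' copied; at substituted positions the backbone (N, CA, C, O, CB) is
#' copied and the side chain beyond CB is rebuilt with ideal bond geometry
#' in the extended rotamer. Unaligned query residues are omitted and
#' listed in the result's provenance. The output is labelled as a
#' threading model, not a homology model.
#'
#' @param template_chain single-chain `dd_structure`.
#' @param query_sequence one-letter query sequence.
#' @param query_resnos residue numbers for the query sequence (defaults to
#'   1..n; pass the domain numbering so face residues keep their labels).
#' @param correspondence optional data.frame(`query_resno`,
#'   `template_resno`); computed by sequence alignment when NULL.
#' @param min_coverage minimum aligned fraction of the query (default 0.8).
#' @return a `dd_structure` (attribute `omitted`: unaligned query resnos).
#' @export
thread_query <- function(template_chain, query_sequence,
                         query_resnos = seq_len(nchar(query_sequence)),
                         correspondence = NULL, min_coverage = 0.8) {
  stopifnot(nchar(query_sequence) == length(query_resnos))
  tmpl_seq <- chain_sequence(template_chain)
  tmpl_resnos <- chain_resnos(template_chain)
  if (is.null(correspondence)) {
    qaa <- strsplit(query_sequence, "")[[1]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query_sequence), Biostrings::AAString(tmpl_seq),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    qi <- cumsum(ap != "-"); ti <- cumsum(as_ != "-")
    keep <- ap != "-" & as_ != "-"
    correspondence <- data.frame(query_resno = query_resnos[qi[keep]],
                                 template_resno = tmpl_resnos[ti[keep]])
  }
  cov <- nrow(correspondence) / nchar(query_sequence)
  if (cov < min_coverage)
    stop(sprintf("threading coverage %.0f%% below the %.0f%% minimum",
                 100 * cov, 100 * min_coverage))
  qaa3 <- aa_one_to_three(strsplit(query_sequence, "")[[1]])
  names(qaa3) <- as.character(query_resnos)
  tat <- template_chain$atoms
  chain_id <- chain_ids(template_chain)[1]
  rows <- vector("list", nrow(correspondence))
  for (i in seq_len(nrow(correspondence))) {
    qr <- correspondence$query_resno[i]
    tr <- correspondence$template_resno[i]
    target <- qaa3[[as.character(qr)]]
    ta <- tat[tat$resno == tr, , drop = FALSE]
    src <- ta$resid[1]
    if (identical(src, target)) {
      out <- ta
      out$resno <- qr
    } else {
      bb <- ta[ta$elety %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
      getxyz <- function(nm) {
        j <- match(nm, bb$elety)
        if (is.na(j)) return(NULL)
        as.numeric(bb[j, c("x", "y", "z")])
      }
      N <- getxyz("N"); CA <- getxyz("CA"); C <- getxyz("C"); O <- getxyz("O")
      if (is.null(N) || is.null(CA) || is.null(C))
        stop("template residue ", tr, " lacks backbone atoms")
      if (is.null(O)) O <- place_atom(N, CA, C, BB_BOND["C_O"],
                                      BB_ANGLE["CA_C_O"], 133)
      out <- residue_atom_rows(chain_id, qr, target, N, CA, C, O)
      ## keep the template CB where both residues have one (preserves the
      ## template chi-1 direction of the backbone frame)
      if (!identical(target, "GLY") && "CB" %in% bb$elety) {
        cb <- getxyz("CB")
        out[out$elety == "CB", c("x", "y", "z")] <- as.list(cb)
        if (nrow(out[!out$elety %in% c("N", "CA", "C", "O", "CB"), ]) > 0) {
          sc <- build_sidechain(target, list(N = N, CA = CA, CB = cb))
          if (!is.null(sc))
            out[match(rownames(sc), out$elety), c("x", "y", "z")] <-
              as.data.frame(sc)
        }
      }
    }
    rows[[i]] <- out
  }
  omitted <- setdiff(query_resnos, correspondence$query_resno)
  s <- dd_structure(do.call(rbind, rows),
                    title = "threading model (synthetic stand-in)",
                    source = sprintf(
                      "thread_query(template=%s, coverage=%.2f)",
                      chain_id, cov))
  attr(s, "omitted") <- omitted
  s
}

#' Layer plan for the extension procedure
#'
#' @param carry named list: layer label -> template chain ids carried into
#'   the assembly unchanged.
#' @param targets template chain ids (in helix order) that receive one
#'   placed query copy each.
#' @param template_order all template chain ids in helix order (defines
#'   helix indices).
#' @return a `dd_layer_plan`.
#' @export
layer_plan <- function(carry, targets, template_order) {
  if (!all(targets %in% template_order))
    stop("plan targets not in template chain order: ",
         paste(setdiff(targets, template_order), collapse = ", "))
  structure(list(carry = carry, targets = targets,
                 template_order = template_order),
            class = "dd_layer_plan")
}

#' Default myddosome-architecture plan from a lattice manifest
#'
#' Carries the MyD88-like and IRAK-4-like layers, targets both IRAK
#' layers with query copies and anchors on the bottom (IRAK-2-like) layer.
#'
#' @param manifest manifest from [make_lattice()].
#' @return list with `plan` (`dd_layer_plan`) and `anchor` (chain ids).
#' @export
myddosome_plan <- function(manifest) {
  ch <- manifest$chains
  labs <- unique(ch$layer)
  if (length(labs) != 3)
    stop("expected a three-layer template, got layers: ",
         paste(labs, collapse = ", "))
  top <- ch$chain[ch$layer == labs[1]]
  mid <- ch$chain[ch$layer == labs[2]]
  bottom <- ch$chain[ch$layer == labs[3]]
  list(plan = layer_plan(carry = stats::setNames(list(top, mid), labs[1:2]),
                         targets = c(mid, bottom),
                         template_order = ch$chain),
       anchor = bottom)
}

#' Build the extended query layer on a template
#'
#' Places one copy of the query domain on every target chain of the plan
#' (sequence-guided CA superposition) and carries the planned template
#' layers unchanged. Query subunits take the helix index of the chain they
#' are placed on.
#'
#' @param query single-chain `dd_structure` (e.g. a threading model).
#' @param template multi-chain template `dd_structure`.
#' @param plan a `dd_layer_plan`.
#' @return a `dd_assembly`.
#' @export
build_extended_layer <- function(query, template, plan) {
  stopifnot(inherits(plan, "dd_layer_plan"))
  idx_of <- stats::setNames(seq_along(plan$template_order),
                            plan$template_order)
  subunits <- list()
  for (lay in names(plan$carry)) {
    for (ch in plan$carry[[lay]]) {
      subunits[[length(subunits) + 1]] <- list(
        chain = ch, layer = lay, helix_index = unname(idx_of[ch]),
        local_index = match(ch, plan$carry[[lay]]),
        structure = get_chain(template, ch),
        provenance = list(note = "template layer, carried unchanged"))
    }
  }
  used <- vapply(subunits, `[[`, "", "chain")
  free <- setdiff(LETTERS, c(used, plan$template_order))
  for (k in seq_along(plan$targets)) {
    tgt <- plan$targets[k]
    placed <- tryCatch(
      superpose_homolog(query, template, template_chain = tgt),
      error = function(e) stop("placement on template chain '", tgt,
                               "' failed: ", conditionMessage(e)))
    sub <- placed$placed
    subunits[[length(subunits) + 1]] <- list(
      chain = free[k], layer = "QUERY", helix_index = unname(idx_of[tgt]),
      local_index = k, structure = sub,
      provenance = list(target_chain = tgt, rmsd = placed$result$rmsd,
                        n_pairs = placed$result$n_pairs,
                        note = "query copy placed by CA superposition"))
  }
  new_assembly(subunits)
}

#' Re-anchor the extended query layer
#'
#' Computes one rigid transform by joint Kabsch superposition of the CA
#' atoms of the first `length(anchor_chains)` query subunits onto the
#' anchor chains of the template (order-respecting), applies it to ALL
#' query subunits, and re-indexes the query layer so its first subunit
#' takes the first anchor chain's helix index. Template layers are
#' untouched; template subunits occupying the anchor positions are not
#' part of the assembly (the query layer replaces them).
#'
#' @param a a `dd_assembly` from [build_extended_layer()].
#' @param template the template `dd_structure`.
#' @param anchor_chains template chain ids of the anchor layer, helix
#'   order.
#' @param template_order all template chain ids in helix order.
#' @return the re-anchored `dd_assembly` (provenance records the anchor
#'   rmsd).
#' @export
reanchor <- function(a, template, anchor_chains,
                     template_order = chain_ids(template)) {
  qs <- query_subunits(a)
  n_anchor <- length(anchor_chains)
  if (length(qs) < n_anchor)
    stop("assembly has ", length(qs), " query subunits; need at least ",
         n_anchor, " to anchor")
  qs <- qs[order(vapply(qs, `[[`, 0, "helix_index"))]
  mob <- NULL; fix <- NULL
  for (i in seq_len(n_anchor)) {
    corr <- align_chains(qs[[i]]$structure, template,
                         template_chain = anchor_chains[i])
    cc <- corresponding_ca(qs[[i]]$structure, template, corr,
                           template_chain = anchor_chains[i])
    if (nrow(cc$query) < 20)
      stop("anchor mismatch on chain '", anchor_chains[i], "': only ",
           nrow(cc$query), " CA pairs")
    mob <- rbind(mob, cc$query); fix <- rbind(fix, cc$template)
  }
  res <- kabsch(mob, fix)
  idx_of <- stats::setNames(seq_along(template_order), template_order)
  shift <- unname(idx_of[anchor_chains[1]]) -
    qs[[1]]$helix_index
  subunits <- lapply(a$subunits, function(s) {
    if (s$layer != "QUERY") return(s)
    s$structure <- transform_structure(s$structure, res$transform)
    s$helix_index <- s$helix_index + shift
    s$provenance$anchor_rmsd <- res$rmsd
    s
  })
  new_assembly(subunits, generator = a$generator)
}

#' One-step octamer extension under a myddosome-like scaffold
#'
#' Convenience wrapper: place a query copy on every subunit of the two
#' IRAK layers, then re-anchor the first query tetramer onto the bottom
#' layer so the extended tetramer sits below the template. The result has
#' the template's top two layers plus the full query layer.
#'
#' @param query single-chain query `dd_structure`.
#' @param template three-layer template.
#' @param manifest lattice manifest (see [make_lattice()]).
#' @return a `dd_assembly`.
#' @export
build_octamer <- function(query, template, manifest) {
  mp <- myddosome_plan(manifest)
  a <- build_extended_layer(query, template, mp$plan)
  reanchor(a, template, mp$anchor,
           template_order = mp$plan$template_order)
}
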