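## Rigid-body superposition and sequence-guided chain correspondence.
## The Kabsch solution is computed from the SVD of the covariance of the
## centred point sets, with the determinant correction that forbids
## reflections.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i ||R m_i + t - f_i||^2` over all rigid motions. Reflections are
#' never returned, including for degenerate (e.g. collinear) inputs.
#'
#' @param mobile N x 3 matrix of coordinates to move.
#' @param fixed N x 3 matrix of target coordinates, paired row-by-row.
#' @return an object of class `dd_superposition`: list with `transform`
#'   (`dd_rigid`), `rmsd` (angstroms), `n_pairs`, and `correspondence`
#'   (a data.frame or NULL when pairing is positional).
#' @export
kabsch <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  stopifnot(ncol(mobile) == 3, ncol(fixed) == 3)
  if (nrow(mobile) != nrow(fixed)) stop("point sets differ in size")
  n <- nrow(mobile)
  if (n < 3) stop("superposition underdetermined: need >= 3 paired points, got ", n)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  M <- sweep(mobile, 2, cm); F <- sweep(fixed, 2, cf)
  H <- crossprod(M, F)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  if (min(sv$d) < 1e-10 * max(sv$d, 1e-30))
    warning("degenerate (near-collinear/planar) point set; rotation may be ill-determined")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cf - R %*% cm)
  tr <- rigid_transform(R, t)
  moved <- apply_rigid(mobile, tr)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(list(transform = tr, rmsd = rmsd, n_pairs = n,
                 correspondence = NULL),
            class = "dd_superposition")
}

#' @export
print.dd_superposition <- function(x, ...) {
  cat("Superposition:", x$n_pairs, "pairs, rmsd",
      format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Sequence-guided residue correspondence between homologous chains
#'
#' Global alignment (Needleman-Wunsch) of the two chain sequences under
#' BLOSUM62 with affine gap penalties (open 10, extend 1); the
#' correspondence is the aligned non-gap column set, reported in chain
#' order as residue numbers of each chain.
#'
#' @param query a single-chain `dd_structure` (or a structure plus
#'   `query_chain`).
#' @param template template structure.
#' @param query_chain,template_chain chain ids (default: first chain).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return data.frame with columns `query_resno`, `template_resno`,
#'   `query_aa`, `template_aa`.
#' @export
align_chains <- function(query, template, query_chain = NULL,
                         template_chain = NULL, gap_open = 10, gap_extend = 1) {
  if (is.null(query_chain)) query_chain <- chain_ids(query)[1]
  if (is.null(template_chain)) template_chain <- chain_ids(template)[1]
  qs <- chain_sequence(query, query_chain)
  ts <- chain_sequence(template, template_chain)
  if (nchar(qs) < 10 || nchar(ts) < 10)
    stop("chains must have >= 10 residues for alignment (",
         nchar(qs), " vs ", nchar(ts), ")")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qs), Biostrings::AAString(ts), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qres <- chain_resnos(query, query_chain)
  tres <- chain_resnos(template, template_chain)
  qi <- cumsum(ap != "-"); ti <- cumsum(as_ != "-")
  keep <- ap != "-" & as_ != "-"
  data.frame(query_resno = qres[qi[keep]],
             template_resno = tres[ti[keep]],
             query_aa = ap[keep], template_aa = as_[keep],
             stringsAsFactors = FALSE)
}

## CA coordinate pairs for a correspondence (rows missing a CA are dropped).
corresponding_ca <- function(query, template, corr, query_chain = NULL,
                             template_chain = NULL) {
  qca <- ca_coords(query, query_chain)
  tca <- ca_coords(template, template_chain)
  qk <- paste0(corr$query_resno, "|")
  tk <- paste0(corr$template_resno, "|")
  ok <- qk %in% rownames(qca) & tk %in% rownames(tca)
  list(query = qca[qk[ok], , drop = FALSE],
       template = tca[tk[ok], , drop = FALSE],
       corr = corr[ok, , drop = FALSE])
}

#' Place a query structure onto a homologous template chain
#'
#' Aligns the query chain sequence to the template chain, superposes the
#' corresponding CA atoms by Kabsch, and returns a transformed copy of the
#' full query structure. The original query is untouched.
#'
#' @param query single-chain `dd_structure` to place.
#' @param template template structure.
#' @param template_chain template chain id (default first).
#' @param min_pairs minimum aligned CA pairs required (default 20).
#' @return list with `placed` (transformed query) and `result`
#'   (`dd_superposition`, correspondence attached).
#' @export
superpose_homolog <- function(query, template, template_chain = NULL,
                              min_pairs = 20) {
  if (is.null(template_chain)) template_chain <- chain_ids(template)[1]
  corr <- align_chains(query, template, template_chain = template_chain)
  cc <- corresponding_ca(query, template, corr,
                         template_chain = template_chain)
  if (nrow(cc$query) < min_pairs)
    stop("too few aligned CA pairs for superposition: ", nrow(cc$query),
         " (minimum ", min_pairs, ")")
  res <- kabsch(cc$query, cc$template)
  res$correspondence <- cc$corr
  list(placed = transform_structure(query, res$transform), result = res)
}
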