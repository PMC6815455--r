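## Bemis-Murcko scaffolds via connection-table pruning + OpenBabel
## canonicalization. The scaffold string is used only as a grouping key for
## scaffold-based splitting; it is canonical within this package (OpenBabel
## canonical SMILES), not guaranteed to match other toolkits' strings.

#' Bemis-Murcko scaffold of a molecule
#'
#' Computes the molecular framework: all ring atoms, plus the linker atoms on
#' paths connecting rings, plus any atom attached to that core by a double or
#' triple bond (so ring/linker carbonyls are retained while ordinary side
#' chains are stripped). Acyclic molecules have the empty scaffold `""` and
#' therefore all fall in one scaffold group.
#'
#' @param smiles A single SMILES string.
#' @return The scaffold as an OpenBabel-canonical SMILES string (`""` for
#'   acyclic molecules).
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(length(smiles) == 1)
  if (!nzchar(trimws(smiles)))
    stop_qsar("empty SMILES", class = "qsar_featurize_error")
  if (canonical_smiles_or_na(smiles) %in% NA)
    stop_qsar("unparseable SMILES '%s'", smiles,
              class = "qsar_featurize_error")
  sdf <- withCallingHandlers(
    tryCatch(ChemmineR::smiles2sdf(smiles),
             error = function(e) stop_qsar("unparseable SMILES '%s'", smiles,
                                           class = "qsar_featurize_error")),
    warning = function(w) invokeRestart("muffleWarning"))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  # molecules with no bonds (single atoms) come back as a degenerate
  # placeholder block: acyclic by construction, empty scaffold
  if (ncol(ab) < 3 || ncol(bb) < 3) return("")
  n <- nrow(ab)
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  order <- as.integer(bb[, 3])

  ## iteratively prune degree-1 atoms: what survives is rings + linkers
  alive <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(edges[alive_edge(edges, alive), ]), nbins = n)
    leaves <- alive & deg <= 1
    if (!any(leaves)) break
    alive[leaves] <- FALSE
  }
  if (!any(alive)) return("")  # acyclic

  ## re-attach atoms multiply bonded to the core (e.g. exocyclic carbonyl O)
  keep <- alive
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (order[i] >= 2) {
      if (alive[a] && !alive[b]) keep[b] <- TRUE
      if (alive[b] && !alive[a]) keep[a] <- TRUE
    }
  }

  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  ekeep <- keep[edges[, 1]] & keep[edges[, 2]]
  sub_edges <- cbind(remap[edges[ekeep, 1]], remap[edges[ekeep, 2]])
  sub_order <- order[ekeep]
  symbols <- sub("_.*$", "", rownames(ab))[idx]
  coords <- ab[idx, 1:3, drop = FALSE]
  sdf_txt <- build_sdf_block(symbols, coords, sub_edges, sub_order)
  can <- ChemmineOB::convertFormat("SDF", "CAN", sdf_txt)
  strsplit(can, "[\t\n]")[[1]][1]
}

#' @noRd
alive_edge <- function(edges, alive) alive[edges[, 1]] & alive[edges[, 2]]

#' @noRd
canonical_smiles_or_na <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN",
                                            paste0(smiles, "\n")),
                  error = function(e) NA_character_)
  if (is.na(out) || !nzchar(trimws(out))) NA_character_
  else strsplit(out, "[\t\n]")[[1]][1]
}

#' Assemble a minimal V2000 SDF block
#' @noRd
build_sdf_block <- function(symbols, coords, edges, order) {
  hdr <- c("scaffold", "  qsarstack", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    length(symbols), nrow(edges))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], symbols)
  bonds <- if (nrow(edges)) sprintf("%3d%3d%3d  0  0  0  0",
                                    edges[, 1], edges[, 2], order)
           else character(0)
  paste(c(hdr, counts, atoms, bonds, "M  END", "$$$$"), collapse = "\n")
}
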