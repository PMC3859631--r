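## Dimer-interface residue mapping by buried surface area or cross-chain
## heavy-atom distance.

## minimum cross-chain heavy-atom distance per residue of each chain
.cross_chain_min_dist <- function(dimer, chain_a, chain_b) {
  a <- dimer$atoms[dimer$atoms$chain == chain_a, , drop = FALSE]
  b <- dimer$atoms[dimer$atoms$chain == chain_b, , drop = FALSE]
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  mind_a <- sqrt(apply(d2, 1, min))
  mind_b <- sqrt(apply(d2, 2, min))
  list(a = tapply(mind_a, factor(.atom_keys(a), levels = unique(.atom_keys(a))), min),
       b = tapply(mind_b, factor(.atom_keys(b), levels = unique(.atom_keys(b))), min))
}

#' Identify dimer-interface residues
#'
#' Two operational definitions of "forming the dimer interface": residues
#' burying surface area on complexation (`delta_sasa`, default, threshold in
#' square Angstrom) or residues with any heavy atom within a cutoff of the
#' other chain (`distance`, threshold in Angstrom). Residues inside the
#' configured excluded ranges are removed from the reported sets.
#'
#' @param dimer two-chain [clc_structure()] (extra chains are ignored with a
#'   warning).
#' @param config an [analysis_config()].
#' @param method "delta_sasa" or "distance".
#' @param threshold numeric; defaults 1.0 (square Angstrom) for `delta_sasa`
#'   and 4.5 (Angstrom) for `distance`.
#' @return object of class `interface_set`: list with `residues` (named list
#'   of residue-key character vectors per chain), `method`, `threshold`,
#'   `detail` (per-residue data.frame with the measured quantity).
#' @export
find_interface_residues <- function(dimer, config = analysis_config(),
                                    method = c("delta_sasa", "distance"),
                                    threshold = NULL) {
  method <- match.arg(method)
  chains <- chain_ids(dimer)
  if (length(chains) < 2) stop("interface mapping needs two chains")
  if (length(chains) > 2) {
    warning("more than 2 chains; using the first two: ",
            paste(chains[1:2], collapse = ", "))
    dimer <- clc_structure(
      dimer$atoms[dimer$atoms$chain %in% chains[1:2], , drop = FALSE],
      title = dimer$title)
    chains <- chains[1:2]
  }
  if (is.null(threshold))
    threshold <- if (method == "delta_sasa") 1.0 else 4.5
  ri <- residue_index(dimer)
  if (method == "delta_sasa") {
    va <- delta_sasa_on_complexation(dimer, chains[1], config)
    vb <- delta_sasa_on_complexation(dimer, chains[2], config)
    value <- c(va, vb)[ri$key]
    member <- value > threshold
  } else {
    md <- .cross_chain_min_dist(dimer, chains[1], chains[2])
    value <- c(md$a, md$b)[ri$key]
    member <- value <= threshold
  }
  detail <- data.frame(key = ri$key, chain = ri$chain, resno = ri$resno,
                       resid = ri$resid, value = as.numeric(value),
                       in_interface = member, stringsAsFactors = FALSE)
  excluded <- .in_excluded_range(detail$chain, detail$resno, config)
  reported <- detail$in_interface & !excluded
  residues <- split(detail$key[reported], detail$chain[reported])
  for (ch in chains) if (is.null(residues[[ch]])) residues[[ch]] <- character(0)
  structure(list(residues = residues[chains], method = method,
                 threshold = threshold, detail = detail),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat("interface_set (", x$method, ", threshold ", x$threshold, "): ",
      paste(vapply(names(x$residues),
                   function(ch) paste0(ch, ":", length(x$residues[[ch]])),
                   character(1)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Is a residue at or near the dimer interface?
#'
#' TRUE for interface residues themselves, and for residues whose minimum
#' heavy-atom distance to any interface residue of the other chain is within
#' the cutoff. Captures positions in the channel mouth sitting close to the
#' subunit boundary without burying surface themselves.
#'
#' @param residue_key residue key "chain:resno".
#' @param dimer two-chain [clc_structure()].
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @param interface optional precomputed [find_interface_residues()] result.
#' @param config an [analysis_config()] used if `interface` is missing.
#' @export
near_interface <- function(residue_key, dimer, cutoff = 6,
                           interface = NULL, config = analysis_config()) {
  ri <- residue_index(dimer)
  if (!residue_key %in% ri$key) stop("unknown residue: ", residue_key)
  if (is.null(interface))
    interface <- find_interface_residues(dimer, config)
  if (residue_key %in% unlist(interface$residues)) return(TRUE)
  this_chain <- ri$chain[ri$key == residue_key]
  other <- setdiff(names(interface$residues), this_chain)
  other_keys <- unlist(interface$residues[other])
  if (length(other_keys) == 0) return(FALSE)
  keys <- .atom_keys(dimer$atoms)
  x1 <- as.matrix(dimer$atoms[keys == residue_key, c("x", "y", "z"), drop = FALSE])
  x2 <- as.matrix(dimer$atoms[keys %in% other_keys, c("x", "y", "z"), drop = FALSE])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  sqrt(max(0, min(d2))) <= cutoff
}
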