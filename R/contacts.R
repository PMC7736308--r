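#' Van der Waals overlap contacts between two atom sets
#'
#' Finds all cross-set atom pairs whose van der Waals spheres interpenetrate
#' by more than \code{overlapThreshold}: overlap = vdW_a + vdW_b - distance
#' > threshold (default 0.4 Angstrom). Hydrogens are excluded. The two sets
#' must already be positioned in a common frame (e.g. a molecule and one of
#' its crystal symmetry mates).
#'
#' @param setA,setB \linkS4class{StructureModel} objects or atom
#'   data.frames.
#' @param overlapThreshold minimum overlap in Angstrom (default 0.4).
#' @param radii named vdW radius table (default Bondi); an atom-level
#'   \code{vdw} column overrides it.
#' @return data.frame of contact pairs with atom identities from both sets,
#'   \code{distance} and \code{overlap} (Angstrom), and a \code{class}
#'   column initialised to \code{NA} (see \code{\link{classifyContacts}}).
#' @export
vdwOverlaps <- function(setA, setB, overlapThreshold = 0.4, radii = .BONDI) {
  a <- if (is(setA, "StructureModel")) setA@atoms else setA
  b <- if (is(setB, "StructureModel")) setB@atoms else setB
  if (!nrow(a) || !nrow(b)) stop("both atom sets must be non-empty")
  a <- a[!toupper(a$element) %in% c("H", "D"), , drop = FALSE]
  b <- b[!toupper(b$element) %in% c("H", "D"), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("both atom sets must be non-empty after removing hydrogens")
  ra <- vdwRadii(a, radii)
  rb <- vdwRadii(b, radii)
  A <- coordsMatrix(a); B <- coordsMatrix(b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  ov <- outer(ra, rb, "+") - d
  hit <- which(ov > overlapThreshold, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  i <- hit[, 1]; j <- hit[, 2]
  data.frame(serialA = a$serial[i], nameA = a$name[i],
             elementA = toupper(a$element[i]),
             resnameA = a$resname[i], chainA = a$chain[i],
             resnoA = a$resno[i],
             serialB = b$serial[j], nameB = b$name[j],
             elementB = toupper(b$element[j]),
             resnameB = b$resname[j], chainB = b$chain[j],
             resnoB = b$resno[j],
             distance = d[hit], overlap = ov[hit],
             class = rep(NA_character_, length(i)), stringsAsFactors = FALSE)
}

# side-chain atoms defining the two ends of a salt bridge
.BASIC_SC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.ACIDIC_SC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.isBasic <- function(resname, name)
  (resname == "LYS" & name %in% .BASIC_SC$LYS) |
  (resname == "ARG" & name %in% .BASIC_SC$ARG)

.isAcidic <- function(resname, name)
  (resname == "ASP" & name %in% .ACIDIC_SC$ASP) |
  (resname == "GLU" & name %in% .ACIDIC_SC$GLU)

#' Classify contact pairs into salt bridges and hydrophobic interactions
#'
#' Annotates pairs from \code{\link{vdwOverlaps}}: \code{salt_bridge} when
#' one atom is a Lys/Arg side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2) and
#' the other an Asp/Glu side-chain carboxylate oxygen (Asp OD1/OD2; Glu
#' OE1/OE2), in either orientation; \code{hydrophobic} when both atoms are
#' carbon; \code{other} otherwise.
#'
#' @param pairs data.frame from \code{\link{vdwOverlaps}}.
#' @return list with \code{pairs} (the input with \code{class} filled) and
#'   \code{counts}, a named vector of per-class counts.
#' @export
classifyContacts <- function(pairs) {
  cls <- rep("other", nrow(pairs))
  if (nrow(pairs)) {
    sb <- (.isBasic(pairs$resnameA, pairs$nameA) &
             .isAcidic(pairs$resnameB, pairs$nameB)) |
      (.isAcidic(pairs$resnameA, pairs$nameA) &
         .isBasic(pairs$resnameB, pairs$nameB))
    cls[pairs$elementA == "C" & pairs$elementB == "C"] <- "hydrophobic"
    cls[sb] <- "salt_bridge"
  }
  pairs$class <- cls
  counts <- c(salt_bridge = sum(cls == "salt_bridge"),
              hydrophobic = sum(cls == "hydrophobic"),
              other = sum(cls == "other"))
  list(pairs = pairs, counts = counts)
}
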