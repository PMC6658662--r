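# Acyl-chain orientational order parameters for united-atom lipids, with
# explicit reconstruction of the two geminal hydrogens on each sp3 chain
# carbon and their prochiral (pro-R / pro-S) assignment.
#
# S_ch = <3 cos^2(theta) - 1> / 2, theta = angle between the reconstructed
# C-H direction and the bilayer normal. S_ch uses direction only; the
# 0.109 nm C-H length matters only for exported hydrogen coordinates.

.CH_BOND <- 0.109
.HCH_HALF <- 0.5 * acos(-1 / 3)  # half the ideal tetrahedral H-C-H angle

.row_normalize <- function(m) m / sqrt(rowSums(m * m))

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Vectorised hydrogen reconstruction over n carbons.
# prev/cur/nxt: n x 3 matrices; kind: "sp3" or "sp2" per row.
# Returns list(proR, proS): n x 3 matrices of H positions.
.reconstruct_h <- function(prev, cur, nxt, kind) {
  b1 <- .row_normalize(prev - cur)
  b2 <- .row_normalize(nxt - cur)
  cr <- .row_cross(b1, b2)
  cr_norm <- sqrt(rowSums(cr * cr))
  if (any(cr_norm < 1e-8)) {
    stop("reconstruct_hydrogens: collinear carbon triplet (carbon row ",
         which(cr_norm < 1e-8)[1], ")")
  }
  u <- cr / cr_norm                       # normal to the C-C-C plane
  b <- .row_normalize(b1 + b2)            # in-plane bisector of the two C-C bonds
  sp2 <- kind == "sp2"
  hr <- -b * cos(.HCH_HALF) + u * sin(.HCH_HALF)
  hs <- -b * cos(.HCH_HALF) - u * sin(.HCH_HALF)
  # sp2: single in-plane hydrogen on the exterior bisector; both prochiral
  # labels report the same vector by construction.
  hr[sp2, ] <- -b[sp2, , drop = FALSE]
  hs[sp2, ] <- -b[sp2, , drop = FALSE]
  list(proR = cur + .CH_BOND * hr, proS = cur + .CH_BOND * hs)
}

#' Reconstruct the geminal hydrogens of a united-atom chain carbon
#'
#' sp3: the two C-H unit vectors are symmetric about the exterior bisector
#' of the two C-C bonds, separated by the ideal tetrahedral H-C-H angle and
#' lying in the plane spanned by that bisector and the normal of the C-C-C
#' plane (for equal bond lengths this is the plane perpendicular to
#' c_next - c_prev through the carbon). sp2: a single in-plane hydrogen on
#' the exterior bisector; both labels return the same position.
#'
#' Prochirality convention: pro-R is the hydrogen with positive scalar
#' triple product det(c_prev - c, c_next - c, H - c). Mirror-imaging the
#' carbons therefore swaps the two labels exactly.
#'
#' @param c_prev,c,c_next coordinates (length 3 or n x 3 matrices), nm.
#' @param kind "sp3" (default) or "sp2", scalar or per-row.
#' @return list with `proR` and `proS` hydrogen positions (same shape as
#'   input), C-H length 0.109 nm.
#' @export
reconstruct_hydrogens <- function(c_prev, c, c_next, kind = "sp3") {
  vec_in <- is.null(dim(c_prev))
  prev <- matrix(c_prev, ncol = 3)
  cur <- matrix(c, ncol = 3)
  nxt <- matrix(c_next, ncol = 3)
  kind <- rep_len(kind, nrow(cur))
  stopifnot(all(kind %in% c("sp3", "sp2")))
  h <- .reconstruct_h(prev, cur, nxt, kind)
  if (vec_in) list(proR = as.vector(h$proR), proS = as.vector(h$proS)) else h
}

#' Acyl-chain definition
#'
#' Names the ordered chain carbons of each tail, the sp2 (double-bond)
#' carbons, the lipid residue name and the bilayer normal axis. The default
#' matches the synthetic DOPC-like lipid: 18 carbons per tail named
#' CA1..CA18 / CB1..CB18 with the C9=C10 double bond.
#'
#' @param sn1,sn2 ordered carbon atom names per tail.
#' @param sp2 atom names of sp2 carbons (must appear as adjacent pairs).
#' @param resname lipid residue name.
#' @param normal_axis 1, 2 or 3 (default 3 = Z).
#' @export
chain_definition <- function(sn1 = paste0("CA", 1:18),
                             sn2 = paste0("CB", 1:18),
                             sp2 = c("CA9", "CA10", "CB9", "CB10"),
                             resname = "DOPC", normal_axis = 3) {
  for (tail in list(sn1, sn2)) {
    pos <- match(intersect(sp2, tail), tail)
    if (length(pos) %% 2 != 0 || (length(pos) == 2 && diff(pos) != 1)) {
      stop("chain_definition: sp2 carbons must form adjacent pairs within a tail")
    }
  }
  structure(list(sn1 = sn1, sn2 = sn2, sp2 = sp2, resname = resname,
                 normal_axis = normal_axis), class = "chain_definition")
}

#' Per-carbon order-parameter profile of the lipid tails
#'
#' For every lipid (residue with the chain-definition residue name), every
#' frame and every interior chain carbon (the first and last carbon lack a
#' neighbour and are excluded), reconstructs the pro-R and pro-S hydrogens
#' and accumulates S = (3 cos^2 theta - 1)/2 against the bilayer normal.
#' Means are taken over lipids and frames; the standard error is computed
#' across lipids (each lipid contributing its own frame-averaged profile).
#'
#' @param traj an `md_trajectory`.
#' @param chain_def a [chain_definition()].
#' @return data.frame of class `order_profile` with columns `tail`,
#'   `carbon` (index along the tail), `atom`, `proR_mean`, `proR_se`,
#'   `proS_mean`, `proS_se`, `n_lipids`. Every value lies in [-0.5, 1].
#' @export
order_parameter <- function(traj, chain_def) {
  top <- traj$topology
  ax <- chain_def$normal_axis
  lip_rows <- which(top$resname == chain_def$resname)
  if (length(lip_rows) == 0) {
    stop("order_parameter: no residues named ", chain_def$resname)
  }
  lip_ids <- unique(paste(top$chain[lip_rows], top$resnum[lip_rows]))
  tails <- list(sn1 = chain_def$sn1, sn2 = chain_def$sn2)
  # per-lipid atom row lookup per tail, validated up front
  lookups <- lapply(lip_ids, function(id) {
    rows <- lip_rows[paste(top$chain[lip_rows], top$resnum[lip_rows]) == id]
    lapply(tails, function(carbons) {
      m <- match(carbons, top$name[rows])
      if (anyNA(m)) {
        stop("order_parameter: lipid ", id, " is missing chain atom ",
             carbons[which(is.na(m))[1]])
      }
      rows[m]
    })
  })
  out <- list()
  for (tname in names(tails)) {
    carbons <- tails[[tname]]
    nc <- length(carbons)
    inner <- 2:(nc - 1)
    kind <- ifelse(carbons[inner] %in% chain_def$sp2, "sp2", "sp3")
    # accumulate per-lipid means (over frames and both H samples share label)
    accR <- matrix(0, length(lip_ids), length(inner))
    accS <- matrix(0, length(lip_ids), length(inner))
    for (li in seq_along(lip_ids)) {
      rows <- lookups[[li]][[tname]]
      sR <- sS <- numeric(length(inner))
      for (f in traj$frames) {
        xyz <- f$xyz[rows, , drop = FALSE]
        h <- .reconstruct_h(xyz[inner - 1, , drop = FALSE],
                            xyz[inner, , drop = FALSE],
                            xyz[inner + 1, , drop = FALSE], kind)
        dR <- .row_normalize(h$proR - xyz[inner, , drop = FALSE])
        dS <- .row_normalize(h$proS - xyz[inner, , drop = FALSE])
        sR <- sR + (3 * dR[, ax]^2 - 1) / 2
        sS <- sS + (3 * dS[, ax]^2 - 1) / 2
      }
      accR[li, ] <- sR / n_frames(traj)
      accS[li, ] <- sS / n_frames(traj)
    }
    nl <- length(lip_ids)
    se <- function(m) if (nl > 1) apply(m, 2, stats::sd) / sqrt(nl) else rep(NA_real_, ncol(m))
    out[[tname]] <- data.frame(
      tail = tname, carbon = inner, atom = carbons[inner],
      proR_mean = colMeans(accR), proR_se = se(accR),
      proS_mean = colMeans(accS), proS_se = se(accS),
      n_lipids = nl
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("order_profile", "data.frame")
  res
}
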