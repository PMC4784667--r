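#' Space-group symmetry for anomalous data
#'
#' Symmetry support covers the 65 Sohncke space groups (the chiral groups in
#' which macromolecules crystallize), via a bundled table of general-position
#' triplets in the standard settings of International Tables Vol. A.
#' Non-Sohncke groups are rejected: anomalous phasing only arises in Sohncke
#' settings.
#'
#' @name spacegroup
NULL

.anomsig_env <- new.env(parent = emptyenv())

load_sg_table <- function() {
  if (!is.null(.anomsig_env$sg_table)) return(.anomsig_env$sg_table)
  path <- system.file("extdata", "sohncke_spacegroups.tsv", package = "anomsig")
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("number", "hm", "n_ops", "triplets"),
                    stringsAsFactors = FALSE)
  .anomsig_env$sg_table <- tab
  tab
}

parse_triplet <- function(triplet) {
  # one symmetry operation "x,y+1/2,-z" -> 3x3 rotation (rows) + translation
  parts <- strsplit(triplet, ",", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 3)
  R <- matrix(0L, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- gsub(" ", "", tolower(parts[i]))
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[terms != ""]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      if (term %in% c("x", "y", "z")) {
        R[i, match(term, c("x", "y", "z"))] <- sign
      } else if (grepl("/", term, fixed = TRUE)) {
        nd <- as.numeric(strsplit(term, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * nd[1] / nd[2]
      } else {
        t[i] <- t[i] + sign * as.numeric(term)
      }
    }
  }
  list(R = R, t = t %% 1)
}

normalize_sg_name <- function(spacegroup) {
  s <- gsub("[ ()]", "", as.character(spacegroup))
  s <- paste0(toupper(substr(s, 1, 1)), substring(s, 2))
  # common short monoclinic symbols -> full unique-axis-b symbols
  aliases <- c(P2 = "P121", P21 = "P1211", C2 = "C121", I2 = "I121")
  if (!is.na(aliases[s])) s <- unname(aliases[s])
  s
}

#' Look up a Sohncke space group
#'
#' @param spacegroup Hermann-Mauguin symbol (e.g. `"P212121"`, spaces and
#'   parentheses ignored) or International Tables number.
#' @return A list with `name`, `number`, and `ops`, a list of symmetry
#'   operations, each a list with integer rotation matrix `R` (acting on row
#'   Miller-index vectors as `h %*% R`) and fractional translation `t`.
#' @export
sg_ops <- function(spacegroup) {
  key <- normalize_sg_name(spacegroup)
  cache <- .anomsig_env$sg_cache
  if (is.null(cache)) { cache <- list(); .anomsig_env$sg_cache <- cache }
  if (!is.null(cache[[key]])) return(cache[[key]])
  tab <- load_sg_table()
  row <- if (grepl("^[0-9]+$", key)) which(tab$number == as.integer(key))
         else which(toupper(tab$hm) == toupper(key))
  if (length(row) != 1) {
    abort(sprintf("'%s' is not a recognised Sohncke space group; anomalous phasing requires a Sohncke (chiral) group", spacegroup))
  }
  trips <- strsplit(tab$triplets[row], ";", fixed = TRUE)[[1]]
  out <- list(name = tab$hm[row], number = tab$number[row],
              ops = lapply(trips, parse_triplet))
  cache[[key]] <- out
  .anomsig_env$sg_cache <- cache
  out
}

# integer key for an hkl triple; valid for |index| < 512
hkl_key <- function(h, k, l) {
  (h + 512) * 1048576 + (k + 512) * 1024 + (l + 512)
}

#' Map Miller indices to the asymmetric unit
#'
#' Each reflection is replaced by a canonical representative of its symmetry
#' orbit, and a flag records whether the observation belongs to the
#' Bijvoet-plus or Bijvoet-minus set of that representative. The canonical
#' representative is the lexicographically greatest index (on h, then k, then
#' l) among all rotational images of the reflection and of its Friedel mate;
#' this convention is recorded in file headers written by the package.
#'
#' @param h,k,l Integer Miller indices (equal-length vectors).
#' @param spacegroup Sohncke space-group symbol or number.
#' @return A tibble with columns `h`, `k`, `l` (canonical ASU indices) and
#'   `friedel_minus` (`TRUE` when the observation is in the Bijvoet-minus
#'   set). Centric reflections are always assigned to the plus set.
#' @export
map_to_asu <- function(h, k, l, spacegroup) {
  sg <- sg_ops(spacegroup)
  H <- cbind(as.integer(h), as.integer(k), as.integer(l))
  n <- nrow(H)
  best_key_p <- rep(-Inf, n); best_key_m <- rep(-Inf, n)
  best_p <- H; best_m <- -H
  for (op in sg$ops) {
    img <- H %*% op$R
    key <- hkl_key(img[, 1], img[, 2], img[, 3])
    upd <- key > best_key_p
    if (any(upd)) { best_p[upd, ] <- img[upd, , drop = FALSE]; best_key_p[upd] <- key[upd] }
    mimg <- -img
    mkey <- hkl_key(mimg[, 1], mimg[, 2], mimg[, 3])
    updm <- mkey > best_key_m
    if (any(updm)) { best_m[updm, ] <- mimg[updm, , drop = FALSE]; best_key_m[updm] <- mkey[updm] }
  }
  minus <- best_key_m > best_key_p
  out <- best_p
  out[minus, ] <- best_m[minus, , drop = FALSE]
  tibble(h = out[, 1], k = out[, 2], l = out[, 3], friedel_minus = minus)
}

#' Is a reflection centric?
#'
#' A reflection is centric when its Friedel mate -h is a rotational image of
#' +h, in which case its phase is symmetry-restricted and it carries no
#' anomalous difference.
#'
#' @inheritParams map_to_asu
#' @return Logical vector.
#' @export
is_centric <- function(h, k, l, spacegroup) {
  sg <- sg_ops(spacegroup)
  H <- cbind(as.integer(h), as.integer(k), as.integer(l))
  target <- hkl_key(-H[, 1], -H[, 2], -H[, 3])
  cen <- rep(FALSE, nrow(H))
  for (op in sg$ops) {
    img <- H %*% op$R
    cen <- cen | (hkl_key(img[, 1], img[, 2], img[, 3]) == target)
  }
  cen
}

#' Expand ASU structure factors to the full limiting sphere
#'
#' Applies `F(h R) = F(h) exp(-2 pi i h.t)` for every symmetry operation and
#' adds Friedel mates with conjugated coefficients (appropriate for synthesis
#' of a real map). Duplicate indices keep their first occurrence.
#'
#' @param hkl Integer matrix (n x 3) of ASU Miller indices.
#' @param f Complex structure factors for those indices.
#' @param spacegroup Sohncke space-group symbol or number.
#' @param friedel Include Friedel mates with conjugate coefficients
#'   (default `TRUE`).
#' @return List with matrix `hkl` and complex vector `f` over the expanded set.
#' @export
expand_to_p1 <- function(hkl, f, spacegroup, friedel = TRUE) {
  sg <- sg_ops(spacegroup)
  blocks_h <- list(); blocks_f <- list()
  i <- 1L
  for (op in sg$ops) {
    img <- hkl %*% op$R
    ph <- exp(-2i * pi * as.numeric(hkl %*% op$t))
    blocks_h[[i]] <- img; blocks_f[[i]] <- f * ph; i <- i + 1L
    if (friedel) {
      blocks_h[[i]] <- -img; blocks_f[[i]] <- Conj(f * ph); i <- i + 1L
    }
  }
  H <- do.call(rbind, blocks_h)
  Fv <- do.call(c, blocks_f)
  keep <- !duplicated(hkl_key(H[, 1], H[, 2], H[, 3]))
  list(hkl = H[keep, , drop = FALSE], f = Fv[keep])
}
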