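#' Binding-energy probability density and mode
#'
#' Gaussian kernel density estimate of an ensemble's binding energies
#' (Silverman's rule-of-thumb bandwidth unless overridden), evaluated on a
#' uniform grid spanning the sample range plus three bandwidths on each
#' side. The mode E_M — the most likely binding energy within the
#' ensemble — is the grid point of maximal density.
#'
#' @param ensemble An `sw_ensemble`, or a bare numeric vector of energies.
#' @param bandwidth Optional kernel bandwidth (h-bond units).
#' @param n_grid Number of grid points (default 512).
#' @return Object of class `sw_density` with `sample`, `grid`, `density`,
#'   `mode` (E_M), `bandwidth` and `degenerate` (TRUE for zero-variance
#'   samples, where E_M is the common value).
#' @export
binding_energy_density <- function(ensemble, bandwidth = NULL,
                                   n_grid = 512) {
  u <- if (inherits(ensemble, "sw_ensemble")) ensemble$energies
       else as.numeric(ensemble)
  if (length(u) < 2) stop("need at least 2 binding energies")
  if (stats::sd(u) == 0) {
    d <- list(sample = u, grid = u[1], density = Inf, mode = u[1],
              bandwidth = 0, degenerate = TRUE)
    class(d) <- "sw_density"
    return(d)
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(u) else bandwidth
  stopifnot(bw > 0)
  kd <- stats::density(u, bw = bw, kernel = "gaussian", n = n_grid,
                       from = min(u) - 3 * bw, to = max(u) + 3 * bw)
  d <- list(sample = u, grid = kd$x, density = kd$y,
            mode = kd$x[which.max(kd$y)], bandwidth = bw,
            degenerate = FALSE)
  class(d) <- "sw_density"
  d
}

#' @export
print.sw_density <- function(x, ...) {
  cat(sprintf("<sw_density> n = %d, E_M = %.3f h-bond units (bw %.3f)%s\n",
              length(x$sample), x$mode, x$bandwidth,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
plot.sw_density <- function(x, ...) {
  plot(x$grid, x$density, type = "l", xlab = "binding energy (h-bond units)",
       ylab = "probability density", ...)
  graphics::abline(v = x$mode, lty = 2)
  invisible(x)
}

# unique residue-residue contacts of one member (well pairs, not clashes)
member_contacts <- function(member) {
  pr <- member$interactions
  pr <- pr[pr$kind != "clash", , drop = FALSE]
  unique(paste(pr$res_a, pr$res_b, sep = "|"))
}

#' Intermolecular residue-residue contact probability map (IPM)
#'
#' A residue pair is in contact within one ensemble member iff at least
#' one qualifying atom pair of those residues lies inside its
#' type-specific interaction well; multiple atom pairs between the same
#' residues count once per member. The map entry is the fraction of
#' ensemble members containing the contact.
#'
#' @param ensemble An `sw_ensemble` whose members carry interaction
#'   tables.
#' @return Object of class `sw_ipm`: probability matrix `P` (rows = fixed
#'   unit residues, columns = mobile), `residues_a`, `residues_b`,
#'   `n_members`, and the long-format `contacts` data frame (res_a,
#'   res_b, count, probability).
#' @export
contact_probability_map <- function(ensemble) {
  stopifnot(inherits(ensemble, "sw_ensemble"))
  n <- length(ensemble$members)
  if (!n) stop("empty ensemble")
  keys <- unlist(lapply(ensemble$members, member_contacts))
  m1 <- ensemble$members[[1]]
  if (!is.null(m1$fixed)) {
    res_a <- sort(unique(residue_ids(m1$fixed$atoms)))
    res_b <- sort(unique(residue_ids(m1$mobile$atoms)))
  } else {
    # synthetic ensembles carry only interaction tables
    all_pr <- do.call(rbind, lapply(ensemble$members, `[[`, "interactions"))
    res_a <- sort(unique(all_pr$res_a))
    res_b <- sort(unique(all_pr$res_b))
  }
  P <- matrix(0, length(res_a), length(res_b),
              dimnames = list(res_a, res_b))
  contacts <- data.frame(res_a = character(), res_b = character(),
                         count = integer(), probability = numeric(),
                         stringsAsFactors = FALSE)
  if (length(keys)) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    contacts <- data.frame(
      res_a = vapply(parts, `[`, "", 1),
      res_b = vapply(parts, `[`, "", 2),
      count = as.integer(tab), stringsAsFactors = FALSE)
    contacts$probability <- contacts$count / n
    sel <- contacts$res_a %in% res_a & contacts$res_b %in% res_b
    P[cbind(contacts$res_a[sel], contacts$res_b[sel])] <-
      contacts$probability[sel]
    contacts <- contacts[order(-contacts$count, contacts$res_a,
                               contacts$res_b), ]
    rownames(contacts) <- NULL
  }
  m <- list(P = P, residues_a = res_a, residues_b = res_b,
            n_members = n, contacts = contacts)
  class(m) <- "sw_ipm"
  m
}

#' @export
print.sw_ipm <- function(x, ...) {
  cat(sprintf("<sw_ipm> %d x %d residues over %d members; %d contacts seen\n",
              length(x$residues_a), length(x$residues_b), x$n_members,
              nrow(x$contacts)))
  invisible(x)
}

#' Hot-spot probabilities over the most frequent contacts
#'
#' Ranks residue-residue contacts by ensemble frequency (ties broken by
#' frequency descending, then residue identifiers ascending), keeps the
#' `subset_size` most frequent (all, if fewer exist), and reports for each
#' residue the probability — over ensemble members — of participating in
#' at least one subset contact. `per_contact = TRUE` instead averages the
#' subset-contact probabilities involving each residue.
#'
#' @param ensemble An `sw_ensemble`.
#' @param subset_size Number of top contacts kept (default 50; `Inf`
#'   keeps all).
#' @param per_contact Alternative averaging (see above).
#' @return Object of class `sw_hotspots`: data frame `table` (residue,
#'   unit, probability, rank) and the retained `subset` of contacts.
#' @export
hotspot_probabilities <- function(ensemble, subset_size = 50,
                                  per_contact = FALSE) {
  ipm <- contact_probability_map(ensemble)
  cts <- ipm$contacts
  if (!nrow(cts)) stop("no intermolecular contacts in the ensemble")
  k <- min(subset_size, nrow(cts))
  sub <- cts[seq_len(k), , drop = FALSE]
  residues <- unique(c(paste0("A|", sub$res_a), paste0("B|", sub$res_b)))
  n <- length(ensemble$members)
  if (per_contact) {
    prob <- vapply(residues, function(rk) {
      side <- substr(rk, 1, 1); rr <- substring(rk, 3)
      m <- if (side == "A") sub$res_a == rr else sub$res_b == rr
      mean(sub$probability[m])
    }, numeric(1))
  } else {
    sub_keys <- paste(sub$res_a, sub$res_b, sep = "|")
    per_member <- lapply(ensemble$members, function(mm) {
      ck <- member_contacts(mm)
      ck <- ck[ck %in% sub_keys]
      if (!length(ck)) return(character(0))
      parts <- strsplit(ck, "|", fixed = TRUE)
      unique(c(paste0("A|", vapply(parts, `[`, "", 1)),
               paste0("B|", vapply(parts, `[`, "", 2))))
    })
    hits <- table(unlist(per_member))
    prob <- stats::setNames(numeric(length(residues)), residues)
    prob[names(hits)] <- as.numeric(hits) / n
  }
  tab <- data.frame(
    residue = substring(residues, 3),
    unit = ifelse(substr(residues, 1, 1) == "A", "fixed", "mobile"),
    probability = unname(prob), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$probability, tab$unit, tab$residue), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  h <- list(table = tab, subset = sub, subset_size = k, n_members = n)
  class(h) <- "sw_hotspots"
  h
}

#' @export
print.sw_hotspots <- function(x, ...) {
  cat(sprintf("<sw_hotspots> top %d contacts over %d members\n",
              x$subset_size, x$n_members))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Representative conformer of an ensemble
#'
#' The member whose binding energy is nearest the density mode E_M; exact
#' ties resolve to the lowest member index.
#'
#' @param ensemble An `sw_ensemble`.
#' @param density Optional precomputed [binding_energy_density()].
#' @return The selected `sw_complex`, with `member_index` attached.
#' @export
representative_conformer <- function(ensemble, density = NULL) {
  stopifnot(inherits(ensemble, "sw_ensemble"))
  if (!length(ensemble$members)) stop("empty ensemble")
  if (length(ensemble$members) == 1) {
    cx <- ensemble$members[[1]]
    cx$member_index <- 1L
    return(cx)
  }
  if (is.null(density)) density <- binding_energy_density(ensemble)
  idx <- which.min(abs(ensemble$energies - density$mode))
  cx <- ensemble$members[[idx]]
  cx$member_index <- idx
  cx
}
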