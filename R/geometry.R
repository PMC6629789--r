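#' Load a coronary vessel-segment table
#'
#' Reads a delimited geometry file (comma-separated, header
#' `name,length_mm,r_prox_mm,r_dist_mm,parent`) describing the large-artery
#' network and returns a `coronary_tree`. Dimensions are given in mm in the
#' file and converted to cm internally. Topology is encoded by the `parent`
#' column; segments with an empty parent are roots.
#'
#' The packaged default geometry (`coronary_table1()`) is a measured human
#' coronary tree of 17 tapered segments with two roots (LMCA and RCA).
#'
#' @param path path to the geometry file.
#' @return an object of class `coronary_tree`: a list with
#'   * `segments`: tibble with columns `name`, `length`, `r_prox`, `r_dist`
#'     (cm), `parent`, `daughters` (list-column), `terminal` (logical),
#'     `supply` (supply location of the vascular bed fed by a terminal:
#'     `"left_ventricle"`, `"right_ventricle"`, `"septum"`, or `NA`);
#'   * `roots`: character vector of root segment names.
#' @export
load_vessel_table <- function(path) {
  seg <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    length_mm = readr::col_double(),
    r_prox_mm = readr::col_double(),
    r_dist_mm = readr::col_double(),
    parent = readr::col_character()
  ))
  required <- c("name", "length_mm", "r_prox_mm", "r_dist_mm", "parent")
  missing_cols <- setdiff(required, names(seg))
  if (length(missing_cols) > 0) {
    abort(paste0("geometry file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(seg) == 0) abort("no segments in geometry file")
  if (anyDuplicated(seg$name)) abort("duplicate segment names")
  if (any(!is.finite(seg$length_mm)) || any(seg$length_mm <= 0)) {
    abort("non-positive segment length")
  }
  if (any(!is.finite(seg$r_prox_mm)) || any(seg$r_prox_mm <= 0) ||
      any(!is.finite(seg$r_dist_mm)) || any(seg$r_dist_mm <= 0)) {
    abort("non-positive segment radius")
  }
  if (any(seg$r_dist_mm > seg$r_prox_mm + 1e-12)) {
    abort("distal radius exceeds proximal radius (vessels must taper)")
  }
  seg$parent[!is.na(seg$parent) & seg$parent == ""] <- NA_character_
  orphan <- !is.na(seg$parent) & !(seg$parent %in% seg$name)
  if (any(orphan)) {
    abort(paste0("orphan segment(s): ", paste(seg$name[orphan], collapse = ", ")))
  }

  segments <- tibble(
    name = seg$name,
    length = seg$length_mm / 10,
    r_prox = seg$r_prox_mm / 10,
    r_dist = seg$r_dist_mm / 10,
    parent = seg$parent
  )
  tree <- new_coronary_tree(segments)
  check_acyclic(tree)
  tree
}

#' Path to the packaged measured coronary geometry
#' @return file path of the default 17-segment geometry table.
#' @export
coronary_table1 <- function() {
  system.file("extdata", "table1.csv", package = "corowave", mustWork = TRUE)
}

# Rebuild derived topology columns (daughters, terminal, supply) from the
# parent column and return a classed tree.
new_coronary_tree <- function(segments) {
  daughters <- lapply(segments$name, function(nm) {
    segments$name[!is.na(segments$parent) & segments$parent == nm]
  })
  segments$daughters <- daughters
  segments$terminal <- lengths(daughters) == 0
  supply <- coronary_supply_map()
  segments$supply <- ifelse(segments$terminal,
                            unname(supply[segments$name]), NA_character_)
  structure(
    list(segments = segments, roots = segments$name[is.na(segments$parent)]),
    class = "coronary_tree"
  )
}

check_acyclic <- function(tree) {
  seg <- tree$segments
  parent_of <- setNames(seg$parent, seg$name)
  for (nm in seg$name) {
    seen <- character()
    cur <- nm
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) abort(paste0("cycle in topology at segment ", cur))
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(tree)
}

#' Supply location of each terminal vascular bed
#'
#' Default mapping of terminal large arteries to the myocardial territory
#' their vascular bed lies in. The territory selects the ventricular pressure
#' and feedback ratio used for the bed's feedback pressure.
#'
#' @return named character vector (segment name -> supply location).
#' @export
coronary_supply_map <- function() {
  c(
    PDA = "left_ventricle", LAD3 = "left_ventricle", LAD4 = "left_ventricle",
    DIAG = "left_ventricle", MARG1 = "left_ventricle",
    MARG2 = "left_ventricle", MARG3 = "left_ventricle",
    PLA = "right_ventricle",
    LAD1 = "septum", LCX3 = "septum"
  )
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat("<coronary_tree> ", nrow(x$segments), " segments, roots: ",
      paste(x$roots, collapse = ", "), "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Split the LMCA trifurcation into two bifurcations
#'
#' The measured left main coronary artery ends in a trifurcation
#' (LAD, LCX, DIAG). Structured-tree style junction handling assumes binary
#' junctions, so the trifurcation is modelled as two adjacent bifurcations:
#' the LMCA bifurcates into DIAG and a short untapered intermediate segment
#' `D2`, which in turn bifurcates into LAD and LCX. The intermediate radius
#' is not recomputed from the branching exponent (the measured radii are not
#' exactly consistent with it); the default is the 0.185 cm intermediate
#' radius with a 0.25 cm length, both overridable.
#'
#' @param tree a `coronary_tree` whose LMCA has three daughters.
#' @param interm_radius radius (cm) of the intermediate segment.
#' @param interm_length length (cm) of the intermediate segment.
#' @param lmca name of the trifurcating segment.
#' @return a `coronary_tree` in which every internal segment has exactly two
#'   daughters; the set of terminal segments is unchanged.
#' @export
split_trifurcation <- function(tree, interm_radius = 0.185,
                               interm_length = 0.25, lmca = "LMCA") {
  seg <- tree$segments
  if (!(lmca %in% seg$name)) abort(paste0(lmca, " not found in tree"))
  dt <- seg$name[!is.na(seg$parent) & seg$parent == lmca]
  if (length(dt) != 3) {
    abort(paste0(lmca, " is not a trifurcation (", length(dt), " daughters)"))
  }
  keep <- if ("DIAG" %in% dt) "DIAG" else dt[which.min(seg$r_prox[match(dt, seg$name)])]
  moved <- setdiff(dt, keep)
  seg$parent[seg$name %in% moved] <- "D2"
  d2 <- tibble(
    name = "D2", length = interm_length,
    r_prox = interm_radius, r_dist = interm_radius, parent = lmca
  )
  seg <- dplyr::bind_rows(seg[, c("name", "length", "r_prox", "r_dist", "parent")],
                          d2)
  out <- new_coronary_tree(seg)
  check_acyclic(out)
  out
}

#' Structured-tree branching parameters
#'
#' Parameters of the self-similar binary tree standing in for each terminal
#' vessel's vascular bed: daughter-to-parent radius ratios `alpha` and
#' `beta`, radius exponent `xi`, asymmetry ratio `gamma`, area ratio `eta`,
#' minimum radius `r_min` (cm) below which branching stops, and
#' length-to-radius ratio `l_rr` of every small vessel.
#'
#' The printed baseline values (alpha = 0.9, beta = 0.6, xi = 2.76,
#' gamma = 0.41, eta = 1.16) are mutually consistent only approximately;
#' [check_branching_relations()] reports the residuals. When `derive_from_xi`
#' is `TRUE` (or when `alpha`/`beta` are `NULL`), `alpha` and `beta` are
#' recomputed from `(gamma, xi)` via the area-ratio relation
#' `alpha = (1 + gamma^(xi/2))^(-1/xi)`, `beta = alpha * sqrt(gamma)`; this
#' is how a change of `xi` (vascular rarefaction) propagates into the tree.
#'
#' @param alpha,beta daughter radius ratios, `0 < beta < alpha < 1`.
#' @param xi radius exponent, in `[2.33, 3]`.
#' @param gamma asymmetry ratio `(r_d2/r_d1)^2`.
#' @param eta area ratio.
#' @param r_min minimum vessel radius (cm); default 10 micrometres.
#' @param l_rr length-to-radius ratio.
#' @param derive_from_xi recompute `alpha`, `beta` from `(gamma, xi)`.
#' @return object of class `structured_tree_params`.
#' @export
structured_tree_params <- function(alpha = 0.9, beta = 0.6, xi = 2.76,
                                   gamma = 0.41, eta = 1.16,
                                   r_min = 1e-3, l_rr = 25,
                                   derive_from_xi = FALSE) {
  if (xi < 2.33 - 1e-9 || xi > 3 + 1e-9) {
    abort("radius exponent xi must lie in [2.33, 3]")
  }
  if (derive_from_xi || is.null(alpha) || is.null(beta)) {
    alpha <- (1 + gamma^(xi / 2))^(-1 / xi)
    beta <- alpha * sqrt(gamma)
  }
  if (!(beta > 0 && beta < alpha && alpha < 1)) {
    abort("need 0 < beta < alpha < 1")
  }
  if (r_min <= 0) abort("r_min must be positive")
  if (l_rr <= 0) abort("l_rr must be positive")
  rel <- abs(alpha^xi + beta^xi - 1)
  if (rel > 0.02) {
    warn(sprintf("alpha^xi + beta^xi deviates from 1 by %.3f (> 2%%)", rel))
  }
  structure(
    list(alpha = alpha, beta = beta, xi = xi, gamma = gamma, eta = eta,
         r_min = r_min, l_rr = l_rr),
    class = "structured_tree_params"
  )
}

#' @export
print.structured_tree_params <- function(x, ...) {
  cat(sprintf(
    "<structured_tree_params> alpha=%.4f beta=%.4f xi=%.3f gamma=%.3f r_min=%g cm l_rr=%g\n",
    x$alpha, x$beta, x$xi, x$gamma, x$r_min, x$l_rr))
  invisible(x)
}

#' Consistency residuals of the branching relations
#'
#' The branching rules link the radius exponent, asymmetry ratio and area
#' ratio: `alpha^xi + beta^xi = 1`, `eta = (1 + gamma) (1 + gamma^(xi/2))^(-2/xi)`
#' and `gamma = (beta/alpha)^2`. Published parameter values satisfy these only
#' to a few percent; this reports the residuals without enforcing them.
#'
#' @param params a [structured_tree_params()] object.
#' @return tibble with columns `relation`, `value`, `target`, `residual`.
#' @export
check_branching_relations <- function(params) {
  p <- params
  v1 <- p$alpha^p$xi + p$beta^p$xi
  v2 <- (1 + p$gamma) * (1 + p$gamma^(p$xi / 2))^(-2 / p$xi)
  v3 <- (p$beta / p$alpha)^2
  tibble(
    relation = c("alpha^xi + beta^xi", "area ratio eta", "asymmetry gamma"),
    value = c(v1, v2, v3),
    target = c(1, p$eta, p$gamma),
    residual = abs(c(v1 - 1, v2 - p$eta, v3 - p$gamma))
  )
}

#' Radius lattice of a structured tree
#'
#' In a self-similar binary tree every vessel's radius is determined by the
#' number of large-daughter (`alpha`) and small-daughter (`beta`) steps taken
#' from the root: `r(i, j) = alpha^i beta^j r_root`. The tree is therefore
#' represented by its radius lattice rather than by enumerating the (up to
#' millions of) individual vessels. Vessels with radius below `r_min` are
#' pruned; vessel length is `l_rr * r`.
#'
#' @param r_root root radius (cm), normally the distal radius of a terminal
#'   large artery.
#' @param params a [structured_tree_params()] object.
#' @return tibble with columns `i`, `j`, `radius` (cm), `length` (cm),
#'   ordered by generation `i + j`. Empty (with a warning) if
#'   `r_root < r_min`.
#' @export
structured_tree_radii <- function(r_root, params) {
  if (r_root <= 0) abort("r_root must be positive")
  p <- params
  tol <- 1 - 1e-12
  if (r_root < p$r_min * tol) {
    warn("r_root below minimum radius: empty structured tree")
    return(tibble(i = integer(), j = integer(),
                  radius = double(), length = double()))
  }
  i_max <- floor(log(r_root / p$r_min) / log(1 / p$alpha) + 1e-9)
  rows <- purrr::map_dfr(0:i_max, function(i) {
    r_i <- p$alpha^i * r_root
    j_max <- floor(log(r_i / p$r_min) / log(1 / p$beta) + 1e-9)
    tibble(i = i, j = 0:j_max, radius = p$beta^(0:j_max) * r_i)
  })
  rows <- rows[rows$radius >= p$r_min * tol, , drop = FALSE]
  rows$length <- p$l_rr * rows$radius
  rows[order(rows$i + rows$j, rows$i), ]
}
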