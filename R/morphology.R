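#' Published axon-segment geometry
#'
#' Lengths and diameters (um) of the anatomical regions of the central
#' auditory-nerve axon for the control condition and the two
#' acoustic-overexposure scenarios:
#' * `AOE1` — channels redistributed evenly over the enlarged regions, so
#'   areal densities shrink while channel number is conserved;
#' * `AOE2` — channels held at their original positions; the nodal gap is
#'   extended by passive `n1` inserts (2 x 2.425 um, so that n1 + node + n1
#'   spans the 6.15 um of the AOE1 node) and the juxtaparanode by passive
#'   `j1` inserts.
#'
#' The tabulated `axon` length is metadata only: the central axonal segment
#' is stretched at build time so the node-to-node spacing equals the
#' configured internode length (see [axon_spec()]).
#'
#' @return A tibble with columns `condition`, `kind`, `length`, `diameter`.
#' @export
region_geometry <- function() {
  tibble::tribble(
    ~condition, ~kind,  ~length, ~diameter,
    "control",  "node",  1.3,    0.8,
    "control",  "PN",    2.34,   0.75,
    "control",  "JP",    5.14,   2.13,
    "control",  "axon", 10.46,   1.25,
    "AOE1",     "node",  6.15,   1.28,
    "AOE1",     "PN",    1.52,   1.23,
    "AOE1",     "JP",    6.23,   1.32,
    "AOE1",     "axon",  9.79,   1.25,
    "AOE2",     "node",  1.3,    1.28,
    "AOE2",     "n1",    2.425,  1.28,
    "AOE2",     "PN",    2.34,   1.23,
    "AOE2",     "JP",    5.14,   2.13,
    "AOE2",     "j1",    1.09,   1.16,
    "AOE2",     "axon",  9.79,   1.25
  )
}

#' Passive membrane properties
#'
#' Specific capacitance (uF cm^-2) and leak conductance (mS cm^-2) of nodal
#' and internodal membrane. Internodal values lump the myelin sheath and the
#' axolemma into a single effective membrane (single-cable model); the
#' thinner post-AOE myelin gives the larger internodal capacitance and leak.
#' Bare (nodal and `n1`) membrane is 1 uF cm^-2 with a 0.2 mS cm^-2 leak.
#'
#' @return A tibble with columns `condition` (`control`/`AOE`),
#'   `membrane` (`node`/`internode`), `cm_specific`, `g_leak`.
#' @export
passive_properties <- function() {
  tibble::tribble(
    ~condition, ~membrane,    ~cm_specific, ~g_leak,
    "control",  "node",       1,            0.2,
    "control",  "internode",  0.0184,       0.01089,
    "AOE",      "node",       1,            0.2,
    "AOE",      "internode",  0.0290,       0.0203
  )
}

#' Lateral surface area of a cylindrical segment
#'
#' @param length,diameter Segment dimensions, um.
#' @return A tibble with `length`, `diameter`, `area_um2` and `area_cm2`
#'   (`area = pi * d * l`).
#' @examples
#' surface_area(1.3, 0.8)  # control node: 3.27 um^2 -> 0.0327 pF at 1 uF/cm^2
#' @export
surface_area <- function(length, diameter) {
  if (any(length < 0) || any(diameter < 0)) {
    rlang::abort("`length` and `diameter` must be non-negative.")
  }
  a <- pi * diameter * length
  tibble::tibble(length = length, diameter = diameter,
                 area_um2 = a, area_cm2 = a * 1e-8)
}

#' Passive length constant of a cylindrical cable
#'
#' \eqn{\lambda = \sqrt{rad \cdot R_m / (2 R_a)}}, where `rad` is the axon
#' radius (cm), `r_m` the specific membrane resistance (Ohm cm^2) and `r_a`
#' the axoplasmic resistivity (Ohm cm).
#'
#' @param radius Axon radius, cm.
#' @param r_m Membrane resistivity, Ohm cm^2 (the reciprocal of the local
#'   leak conductance per area).
#' @param r_a Axoplasmic resistivity, Ohm cm (70 throughout this model).
#' @return Length constant(s) in cm.
#' @examples
#' # control internodal axon, d = 1.25 um, g_leak = 10.89 uS/cm2:
#' length_constant(0.625e-4, 1 / 10.89e-6, 70)  # ~0.20 cm
#' @export
length_constant <- function(radius, r_m, r_a = 70) {
  if (any(radius <= 0) || any(r_m <= 0) || any(r_a <= 0)) {
    rlang::abort("`radius`, `r_m` and `r_a` must all be positive.")
  }
  sqrt(radius * r_m / (2 * r_a))
}

#' Channel-number-conserving density rescale factor
#'
#' When a membrane region changes size but keeps its total channel count,
#' the areal density scales by the ratio of the old to the new lateral area,
#' so that density x area is conserved exactly. `mode = "length"` instead
#' scales by the length ratio alone (an alternative reading of "even
#' distribution along the altered length").
#'
#' @param control,aoe One-row data frames (or lists) with `kind`, `length`
#'   and `diameter` describing the same region before and after remodeling.
#' @param mode `"area"` (default, conserves total conductance) or
#'   `"length"`.
#' @return A single dimensionless scale factor to apply to the control
#'   density.
#' @examples
#' ctrl <- list(kind = "node", length = 1.3, diameter = 0.8)
#' aoe <- list(kind = "node", length = 6.15, diameter = 1.28)
#' density_rescale_factor(ctrl, aoe)  # ~0.132
#' @export
density_rescale_factor <- function(control, aoe, mode = c("area", "length")) {
  mode <- match.arg(mode)
  if (!identical(control$kind, aoe$kind)) {
    rlang::abort("`control` and `aoe` must describe the same region kind.")
  }
  if (any(c(control$length, control$diameter, aoe$length, aoe$diameter) <= 0)) {
    rlang::abort("region dimensions must be positive.")
  }
  switch(mode,
    area   = (control$diameter * control$length) / (aoe$diameter * aoe$length),
    length = control$length / aoe$length
  )
}

inr_kind_order <- function(condition) {
  if (condition == "AOE2") c("n1", "PN", "JP", "j1", "axon", "j1", "JP", "PN", "n1")
  else c("PN", "JP", "axon", "JP", "PN")
}

#' Build a periodic axon specification
#'
#' Assembles the ordered region chain of the central axon: `n_nodes` nodes of
#' Ranvier alternating with internodal regions (INRs), each INR holding two
#' paranodes (PN), two juxtaparanodes (JP) and a central axonal segment
#' (plus passive `n1`/`j1` inserts in the AOE2 scenario). The central axonal
#' segment of every INR is stretched so that the node-center to node-center
#' spacing equals `internode_length` plus the local node length.
#'
#' Channel placement: Nav and Kv3.1 at the node, Kv1.1 (I_LT) in the JP by
#' default (`lt_site = "PN"` moves it to the paranode); `n1` and `j1`
#' inserts carry no voltage-gated channels. Under AOE1, nodal and JP
#' densities are rescaled by [density_rescale_factor()] so total channel
#' number matches control; under AOE2 densities stay at control values over
#' the (repositioned) control-sized regions.
#'
#' `affected_inrs` selects which internodes (1-based, 1 is most proximal)
#' carry the AOE geometry; the rest stay control. A node takes the AOE nodal
#' geometry when at least one adjacent INR is affected. With
#' `affected_inrs = integer(0)` any condition reduces to the control cable.
#'
#' @param condition `"control"`, `"AOE1"` or `"AOE2"`.
#' @param internode_length Node-to-node spacing handled by each INR, um.
#' @param n_nodes Number of nodes (default 7: nodes 0..6, 6 internodes).
#' @param affected_inrs Integer vector of INR indices carrying AOE geometry;
#'   default all for AOE conditions, none for control.
#' @param params A [channel_params()] object.
#' @param ra Axoplasmic resistivity, Ohm cm.
#' @param aoe1_scaling Passed to [density_rescale_factor()] as `mode`.
#' @param lt_site `"JP"` (default) or `"PN"`: region expressing I_LT.
#' @return A tibble of class `axon_spec`, one row per region instance, with
#'   columns `kind`, `node` (node number or NA), `inr` (INR number or NA),
#'   `aoe` (logical), `length`, `diameter` (um), `cm_specific` (uF cm^-2),
#'   `g_leak`, `g_na`, `g_ht`, `g_lt` (mS cm^-2). Attributes carry the
#'   build arguments.
#' @examples
#' axon_spec("control")
#' axon_spec("AOE1", affected_inrs = integer(0))  # identical to control
#' @export
axon_spec <- function(condition = c("control", "AOE1", "AOE2"),
                      internode_length = 100, n_nodes = 7,
                      affected_inrs = NULL,
                      params = channel_params(),
                      ra = 70,
                      aoe1_scaling = c("area", "length"),
                      lt_site = c("JP", "PN")) {
  condition <- match.arg(condition)
  aoe1_scaling <- match.arg(aoe1_scaling)
  lt_site <- match.arg(lt_site)
  if (n_nodes < 2) rlang::abort("`n_nodes` must be at least 2.")
  n_inr <- n_nodes - 1
  if (is.null(affected_inrs)) {
    affected_inrs <- if (condition == "control") integer(0) else seq_len(n_inr)
  }
  affected_inrs <- as.integer(affected_inrs)
  if (any(affected_inrs < 1 | affected_inrs > n_inr)) {
    rlang::abort(sprintf("`affected_inrs` must be inside 1..%d.", n_inr))
  }

  geom <- region_geometry()
  pas <- passive_properties()
  gdim <- function(cond, kind) geom[geom$condition == cond & geom$kind == kind, ]
  ipas <- function(cond) pas[pas$condition == cond & pas$membrane == "internode", ]

  lt_density <- function(cond) {
    if (condition == "AOE1" && cond == "AOE1") {
      params$g_lt * density_rescale_factor(
        gdim("control", lt_site), gdim("AOE1", lt_site), mode = aoe1_scaling)
    } else params$g_lt
  }
  node_density_scale <- if (condition == "AOE1") {
    density_rescale_factor(gdim("control", "node"), gdim("AOE1", "node"),
                           mode = aoe1_scaling)
  } else 1

  region_row <- function(kind, cond_geo, aoe) {
    g <- gdim(cond_geo, kind)
    bare <- kind %in% c("node", "n1")
    p <- if (bare) pas[pas$membrane == "node", ][1, ] else
      ipas(if (aoe) "AOE" else "control")
    dens <- c(g_na = 0, g_ht = 0, g_lt = 0)
    if (kind == "node") {
      s <- if (aoe && condition == "AOE1") node_density_scale else 1
      dens["g_na"] <- params$g_na * s
      dens["g_ht"] <- params$g_ht * s
    }
    if (kind == lt_site) {
      dens["g_lt"] <- if (aoe) lt_density("AOE1") else lt_density("control")
    }
    tibble::tibble(kind = kind, aoe = aoe, length = g$length, diameter = g$diameter,
                   cm_specific = p$cm_specific, g_leak = p$g_leak,
                   g_na = dens[["g_na"]], g_ht = dens[["g_ht"]], g_lt = dens[["g_lt"]])
  }

  build_inr <- function(i) {
    aoe <- i %in% affected_inrs
    cond_geo <- if (aoe) condition else "control"
    kinds <- inr_kind_order(if (aoe) condition else "control")
    rows <- dplyr::bind_rows(lapply(kinds, region_row, cond_geo = cond_geo, aoe = aoe))
    ax_len <- internode_length - sum(rows$length[rows$kind != "axon"])
    if (ax_len <= 0) {
      rlang::abort(sprintf(
        "internode_length = %g um cannot fit the %g um of fixed PN/JP regions.",
        internode_length, sum(rows$length[rows$kind != "axon"])))
    }
    rows$length[rows$kind == "axon"] <- ax_len
    rows$inr <- i
    rows
  }

  node_is_aoe <- function(i) {
    condition != "control" && any(c(i - 1, i) %in% affected_inrs)
  }
  out <- list()
  for (i in seq_len(n_nodes)) {
    aoe_n <- node_is_aoe(i)
    nd <- region_row("node", if (aoe_n) condition else "control", aoe_n)
    nd$node <- i - 1L
    out[[length(out) + 1]] <- nd
    if (i <= n_inr) out[[length(out) + 1]] <- build_inr(i)
  }
  spec <- dplyr::bind_rows(out)
  spec <- spec[, c("kind", "node", "inr", "aoe", "length", "diameter",
                   "cm_specific", "g_leak", "g_na", "g_ht", "g_lt")]
  structure(spec,
            class = c("axon_spec", class(tibble::tibble()))
            , condition = condition, internode_length = internode_length,
            n_nodes = n_nodes, affected_inrs = affected_inrs, ra = ra,
            params = params, lt_site = lt_site, aoe1_scaling = aoe1_scaling)
}

#' Discretize an axon specification into isopotential compartments
#'
#' Splits every region into compartments no longer than
#' `max_lambda_fraction` times the local passive length constant, so that
#' each compartment can be treated as isopotential. Compartment capacitance,
#' leak and channel conductances are the specific values times the lateral
#' area; the axial resistance between adjacent compartments is the sum of
#' the two half-compartment resistances \eqn{4 R_a (l/2) / (\pi d^2)}.
#'
#' @param spec An [axon_spec()] tibble.
#' @param max_lambda_fraction Maximum compartment length as a fraction of
#'   the local length constant (default 0.1).
#' @return A tibble of class `axon_cable`, one row per compartment:
#'   `comp`, `kind`, `node`, `inr`, `length`, `diameter`, `position` (center,
#'   um from the proximal end), `area_cm2`, `c_nF`, `g_leak_uS`, `g_na_uS`,
#'   `g_ht_uS`, `g_lt_uS`, and `r_axial_MOhm` (to the next compartment; NA in
#'   the last row). Attribute `node_comp` holds the compartment index (1-based)
#'   of each node's central compartment, in node order.
#' @examples
#' cable <- axon_spec("control") |> discretize()
#' nrow(cable)
#' @export
discretize <- function(spec, max_lambda_fraction = 0.1) {
  stopifnot(inherits(spec, "axon_spec"))
  if (max_lambda_fraction <= 0) rlang::abort("`max_lambda_fraction` must be positive.")
  ra <- attr(spec, "ra")

  lam_um <- length_constant(spec$diameter / 2 * 1e-4, 1 / (spec$g_leak * 1e-3), ra) * 1e4
  n_comp <- pmax(1L, ceiling(spec$length / (max_lambda_fraction * lam_um)))

  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- n_comp[i]
    tibble::tibble(
      region = i, kind = spec$kind[i], node = spec$node[i], inr = spec$inr[i],
      sub = seq_len(n), n_sub = n,
      length = spec$length[i] / n, diameter = spec$diameter[i],
      cm_specific = spec$cm_specific[i], g_leak = spec$g_leak[i],
      g_na = spec$g_na[i], g_ht = spec$g_ht[i], g_lt = spec$g_lt[i]
    )
  })
  cab <- dplyr::bind_rows(rows)
  cab$comp <- seq_len(nrow(cab))
  cab$position <- cumsum(cab$length) - cab$length / 2
  cab$area_cm2 <- pi * cab$diameter * cab$length * 1e-8
  cab$c_nF <- cab$cm_specific * cab$area_cm2 * 1e3
  cab$g_leak_uS <- cab$g_leak * cab$area_cm2 * 1e3
  cab$g_na_uS <- cab$g_na * cab$area_cm2 * 1e3
  cab$g_ht_uS <- cab$g_ht * cab$area_cm2 * 1e3
  cab$g_lt_uS <- cab$g_lt * cab$area_cm2 * 1e3
  r_half <- 4 * ra * (cab$length * 1e-4 / 2) / (pi * (cab$diameter * 1e-4)^2) / 1e6
  cab$r_axial_MOhm <- c(r_half[-nrow(cab)] + r_half[-1], NA_real_)

  node_comp <- vapply(sort(unique(stats::na.omit(cab$node))), function(nd) {
    idx <- which(cab$node == nd & !is.na(cab$node))
    idx[ceiling(length(idx) / 2)]
  }, integer(1))

  out <- cab[, c("comp", "kind", "node", "inr", "length", "diameter", "position",
                 "area_cm2", "c_nF", "g_leak_uS", "g_na_uS", "g_ht_uS", "g_lt_uS",
                 "r_axial_MOhm")]
  structure(out,
            class = c("axon_cable", class(tibble::tibble())),
            node_comp = node_comp, ra = ra,
            condition = attr(spec, "condition"),
            internode_length = attr(spec, "internode_length"),
            n_nodes = attr(spec, "n_nodes"),
            affected_inrs = attr(spec, "affected_inrs"),
            params = attr(spec, "params"),
            max_lambda_fraction = max_lambda_fraction)
}
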