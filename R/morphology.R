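# Reduced parametric Purkinje-cell morphology.
#
# The cell is built from cylindrical cable sections in four regions: soma,
# axon initial segment (AIS), three main dendritic limbs, and 22 spiny
# branches. Each spiny branch is a compact fan: a short stem section rooted
# on its limb (so exactly one compartment adjoins the parent main dendrite)
# carrying a set of parallel short tip branchlets that hold the branch
# membrane area. The fan keeps tip-to-soma path lengths short (tens of um),
# which is what lets a branch spike decay steeply once it crosses the stem
# into the main-dendrite sink. Branch membrane areas and stem diameters are
# heterogeneous, which is what makes source/sink ratios - and hence
# dendritic-spike capability - differ across branches.

#' Default morphology configuration
#'
#' Geometry of the reduced Purkinje cell: global passive constants, soma/AIS
#' cylinders, the three main limbs with their branch attachment points, and
#' the per-branch heterogeneity schedule (total membrane area and stem
#' diameter per branch). Branches 1-8 sit on the left limb, 9-13 on the
#' middle limb, 14-22 on the right limb. Branch 8 carries the largest
#' area-to-coupling ratio and is the canonical high-excitability branch;
#' branch 12 is the most soma-efficient spiking branch (short electrotonic
#' path on the middle limb).
#'
#' Spiny sections use an elevated specific capacitance (and scaled leak) to
#' absorb spine membrane, the usual spine-collapse approximation; spines are
#' not modelled explicitly.
#'
#' @return nested list with elements `passive`, `soma`, `ais`, `limbs`,
#'   `branches` (data.frame), `subtree`, `discretization`
#' @export
morphology_config <- function() {
  branches <- data.frame(
    branch_id = 1:22,
    limb_id   = c(rep(1L, 8), rep(2L, 5), rep(3L, 9)),
    attach    = c(0.15, 0.25, 0.35, 0.45, 0.55, 0.70, 0.85, 1.00,   # left
                  0.20, 0.40, 0.60, 0.45, 0.90,                      # middle
                  0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.80, 0.90, 1.00), # right
    area_um2  = c(800, 850, 500, 550, 450, 700, 750, 1500,
                  750, 800, 820, 1400, 500,
                  480, 520, 780, 800, 430, 460, 440, 1350, 1300),
    stem_diam = c(0.90, 0.90, 1.60, 1.70, 1.60, 1.00, 1.00, 0.69,
                  0.95, 0.95, 0.90, 0.72, 1.65,
                  1.70, 1.65, 0.95, 0.90, 1.75, 1.70, 1.75, 0.72, 0.73),
    stem_len  = c(14, 14, 6, 6, 6, 16, 16, 28,
                  14, 14, 14, 28, 6,
                  6, 6, 14, 14, 6, 6, 6, 28, 28)
  )
  list(
    passive = list(ra = 120, cm_main = 0.8, cm_spiny = 1.1),  # Ohm cm, uF/cm2
    soma  = list(length = 20, diam = 20),
    ais   = list(length = 20, diam = 1.2),
    limbs = data.frame(limb_id = 1:3,
                       length = c(120, 80, 140),
                       diam   = c(2.6, 2.6, 2.6)),
    branches = branches,
    subtree = list(tip_len = 16),
    discretization = list(max_len = 25, tip_nseg = 3)
  )
}

#' Build the reduced Purkinje-cell section tree
#'
#' Returns one row per cable section: 1 soma (the root), 1 AIS, 3 main-limb
#' cables, and 22 spiny fans (stem + parallel tip branchlets). Tip count and
#' length inside each branch are solved so that the branch surface area
#' matches the configured `area_um2` exactly.
#'
#' @param config list as returned by [morphology_config()]
#' @return data.frame of sections with columns `id`, `parent_id`,
#'   `parent_pos`, `length`, `diam`, `region`, `branch_id`, `limb_id`,
#'   `kind` (`stem`/`child`/`tip` for spiny sections)
#' @export
build_reduced_pc <- function(config = morphology_config()) {
  br <- config$branches
  if (nrow(br) != 22L || !identical(sort(br$branch_id), 1:22))
    stop("branch schedule must define branch ids 1..22")
  counts <- table(br$limb_id)
  if (sum(counts) != 22L)
    stop("per-limb branch counts must sum to 22")
  if (any(br$area_um2 <= 0) || any(br$stem_diam <= 0))
    stop("branch areas and stem diameters must be positive")

  rows <- list()
  add <- function(id, parent_id, parent_pos, length, diam, region,
                  branch_id = NA_integer_, limb_id = NA_integer_,
                  kind = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, parent_id = parent_id, parent_pos = parent_pos,
      length = length, diam = diam, region = region,
      branch_id = branch_id, limb_id = limb_id, kind = kind,
      stringsAsFactors = FALSE)
  }

  add("soma", NA_character_, NA_real_, config$soma$length, config$soma$diam, "soma")
  add("ais", "soma", 0, config$ais$length, config$ais$diam, "AIS")
  for (l in 1:3) {
    lb <- config$limbs[config$limbs$limb_id == l, ]
    add(sprintf("limb%d", l), "soma", 1, lb$length, lb$diam, "main",
        limb_id = l)
  }

  st <- config$subtree
  for (i in seq_len(nrow(br))) {
    b <- br[i, ]
    d <- b$stem_diam
    # area = pi*d*(stem_len + n_tip*tip_len); solve tip count for the target
    cable <- b$area_um2 / (pi * d)
    n_tip <- max(2L, as.integer(round((cable - b$stem_len) / st$tip_len)))
    tip_len <- (cable - b$stem_len) / n_tip
    if (tip_len <= 0) stop(sprintf("branch %d area too small for its stem", b$branch_id))
    # heterogeneous branchlet lengths (fixed cycle, mean preserved): local
    # input impedance varies across branchlets, so random synapse placement
    # produces trial-to-trial variation in spike initiation
    wts <- rep_len(c(0.45, 1.3, 0.7, 1.55, 1.0), n_tip)
    wts <- wts / mean(wts)
    stem_id <- sprintf("b%02d_stem", b$branch_id)
    add(stem_id, sprintf("limb%d", b$limb_id), b$attach,
        b$stem_len, d, "stem", b$branch_id, b$limb_id, "stem")
    for (k in seq_len(n_tip)) {
      add(sprintf("b%02d_t%02d", b$branch_id, k), stem_id, 1,
          tip_len * wts[k], d, "spiny", b$branch_id, b$limb_id, "tip")
    }
  }
  sec <- do.call(rbind, rows)
  if (any(sec$length <= 0) || any(sec$diam <= 0))
    stop("all sections need positive length and diameter")
  if (sum(is.na(sec$parent_id)) != 1L)
    stop("exactly one root section (the soma) is required")
  sec
}

#' Closed-form axial resistance of a cylinder
#'
#' `r = 4 rho L / (pi d^2)`, converted to megaohms.
#'
#' @param length um
#' @param diam um
#' @param ra axial resistivity, Ohm cm
#' @return resistance in MOhm
#' @export
cylinder_axial_resistance <- function(length, diam, ra) {
  4 * ra * length / (pi * diam^2) * 1e-2
}

#' Discretize a section tree into a compartment graph
#'
#' Splits every section into compartments of at most `max_len` um (overrides
#' allow a fixed compartment count for named sections, e.g. a finer tip for
#' two-point axial-current recording). Compartment centres sit at fractions
#' `(i - 1/2)/nseg`; the axial resistance to the parent compartment is the
#' centre-to-centre cylindrical resistance (half segments on each side at
#' section boundaries). The returned compartment order is parent-before-child
#' (Hines order) so the implicit tree solve runs in one sweep.
#'
#' @param sections data.frame from [build_reduced_pc()]
#' @param rule list with `max_len` (um) and optional named integer vector
#'   `overrides` mapping section id to compartment count
#' @param passive list with `ra` (Ohm cm), `cm_main`, `cm_spiny` (uF/cm2)
#' @return object of class `pc_graph`
#' @export
discretize <- function(sections, rule = list(max_len = 25),
                       passive = morphology_config()$passive) {
  if (any(sections$length <= 0)) stop("zero-length section")
  overrides <- rule$overrides %||% integer()
  if (length(overrides) && !all(names(overrides) %in% sections$id))
    stop("discretization override references unknown section: ",
         paste(setdiff(names(overrides), sections$id), collapse = ", "))

  n_per <- pmax(1L, as.integer(ceiling(sections$length / (rule$max_len %||% 25))))
  if (length(overrides))
    n_per[match(names(overrides), sections$id)] <- as.integer(overrides)

  comps <- vector("list", nrow(sections))
  sec_first <- integer(nrow(sections))  # comp id of first (proximal) comp
  sec_last <- integer(nrow(sections))
  next_id <- 0L
  for (s in seq_len(nrow(sections))) {
    ns <- n_per[s]
    sec <- sections[s, ]
    seg_len <- sec$length / ns
    seg_area <- pi * sec$diam * seg_len
    cm <- if (sec$region %in% c("spiny", "stem")) passive$cm_spiny else passive$cm_main
    ids <- next_id + seq_len(ns)
    next_id <- next_id + ns

    parent <- integer(ns)
    ra_vec <- numeric(ns)
    if (ns > 1) {
      parent[2:ns] <- ids[1:(ns - 1)]
      ra_vec[2:ns] <- cylinder_axial_resistance(seg_len, sec$diam, passive$ra)
    }
    if (is.na(sec$parent_id)) {
      parent[1] <- 0L
      ra_vec[1] <- NA_real_
    } else {
      ps <- match(sec$parent_id, sections$id)
      psec <- sections[ps, ]
      np <- n_per[ps]
      # parent compartment containing parent_pos
      pidx <- min(np, max(1L, ceiling(sec$parent_pos * np + 1e-9)))
      pcomp <- sec_first[ps] + pidx - 1L
      parent[1] <- pcomp
      half_child <- cylinder_axial_resistance(seg_len / 2, sec$diam, passive$ra)
      half_parent <- cylinder_axial_resistance(psec$length / np / 2, psec$diam,
                                               passive$ra)
      ra_vec[1] <- half_child + half_parent
    }
    comps[[s]] <- data.frame(
      id = ids, section_id = sec$id, seg = seq_len(ns),
      pos = (seq_len(ns) - 0.5) / ns,
      parent = parent, ra = ra_vec, area = seg_area,
      len = seg_len, diam = sec$diam, cm = cm,
      region = sec$region, branch_id = sec$branch_id, limb_id = sec$limb_id,
      stringsAsFactors = FALSE)
    sec_first[s] <- ids[1]
    sec_last[s] <- ids[ns]
  }
  cg <- do.call(rbind, comps)
  rownames(cg) <- NULL

  # path distance from the soma centre to each compartment centre
  dist <- numeric(nrow(cg))
  seg_half <- cg$len / 2
  for (i in seq_len(nrow(cg))) {
    p <- cg$parent[i]
    dist[i] <- if (p == 0L) 0 else dist[p] + seg_half[p] + seg_half[i]
  }
  cg$dist_soma <- dist

  branch_index <- split(cg$id[!is.na(cg$branch_id)],
                        cg$branch_id[!is.na(cg$branch_id)])
  conn <- vapply(branch_index, function(ids) min(ids), numeric(1))
  g <- list(comps = cg, sections = sections, n = nrow(cg),
            branch_index = branch_index,
            connection_segment = setNames(as.integer(conn), names(conn)),
            soma = sec_first[is.na(sections$parent_id)][1],
            passive = passive)
  class(g) <- "pc_graph"
  g
}

#' @export
print.pc_graph <- function(x, ...) {
  cat(sprintf("pc_graph: %d compartments, %d sections, %d branches\n",
              x$n, nrow(x$sections), length(x$branch_index)))
  cat(sprintf("total membrane area: %.0f um2\n", sum(x$comps$area)))
  invisible(x)
}

#' Axial path resistance between two compartments
#'
#' Sum of centre-to-centre axial resistances along the unique tree path.
#'
#' @param graph `pc_graph`
#' @param a,b compartment ids
#' @return resistance in MOhm
#' @export
axial_path_resistance <- function(graph, a, b) {
  if (a == b) return(0)
  cg <- graph$comps
  anc <- function(i) {
    path <- i
    while (cg$parent[i] != 0L) {
      i <- cg$parent[i]
      path <- c(path, i)
    }
    path
  }
  pa <- anc(a)
  pb <- anc(b)
  common <- intersect(pa, pb)[1]
  ra <- graph$comps$ra
  sum_path <- function(path) {
    stopifnot(common %in% path)
    idx <- path[seq_len(match(common, path) - 1L)]
    sum(ra[idx])
  }
  sum_path(pa) + sum_path(pb)
}

#' Per-branch geometry summary
#'
#' One row per spiny branch: total membrane area, the connection-segment
#' compartment (the unique compartment adjoining the parent main dendrite),
#' and its path distance to the soma centre.
#'
#' @param graph `pc_graph`
#' @return data.frame with columns `branch_id`, `area_um2`,
#'   `connection_segment`, `dist_soma_um`
#' @export
branch_geometry_summary <- function(graph) {
  cg <- graph$comps
  ids <- sort(as.integer(names(graph$branch_index)))
  out <- lapply(ids, function(b) {
    members <- graph$branch_index[[as.character(b)]]
    conn <- graph$connection_segment[[as.character(b)]]
    data.frame(branch_id = b,
               area_um2 = sum(cg$area[members]),
               connection_segment = conn,
               dist_soma_um = cg$dist_soma[conn])
  })
  do.call(rbind, out)
}

#' Export a compartment graph as SWC-like plain text
#'
#' Columns: `id`, `type` (1 soma, 2 AIS, 3 main dendrite, 4 spiny dendrite),
#' `x` (path distance to soma, a placeholder for a 3D position), `radius`,
#' `parent` (-1 for the root). Read back with [read_swc_like()].
#'
#' @param graph `pc_graph`
#' @param path output file
#' @return invisibly, the exported data.frame
#' @export
write_swc_like <- function(graph, path) {
  cg <- graph$comps
  type <- c(soma = 1L, AIS = 2L, main = 3L, spiny = 4L, stem = 5L)[cg$region]
  df <- data.frame(id = cg$id, type = unname(type),
                   x = round(cg$dist_soma, 4), radius = cg$diam / 2,
                   parent = ifelse(cg$parent == 0L, -1L, cg$parent))
  write.table(df, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_swc_like
#' @export
read_swc_like <- function(path) {
  df <- read.table(path, col.names = c("id", "type", "x", "radius", "parent"))
  df
}

#' @importFrom stats setNames
NULL
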