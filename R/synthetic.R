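#' Parameters for the synthetic airway-tree generator
#'
#' The generator emulates segmented centerline trees: a recursive
#' dichotomous tree grown downward from the trachea, each branch a densely
#' sampled polyline with uniform arc-length spacing (the vertex-count length
#' proxy is only meaningful at fixed sampling density, so the spacing is
#' enforced exactly and stamped into provenance). Upward deflections -
#' short sub-segments where the branch bends to ascend before resuming its
#' descent - are inserted as Poisson events per branch; they are what the
#' upwards-complexity descriptor detects.
#'
#' @param generations number of branching generations (>= 1); 1 gives a
#'   single path.
#' @param branch_length_mm c(mean, sd) of branch length at generation 0, mm.
#' @param branching_angle_deg c(mean, sd) of the child-branch deviation from
#'   the parent direction, degrees.
#' @param upward_turn_rate expected upward deflections per branch (Poisson).
#' @param node_spacing_mm uniform arc-length step between centerline nodes.
#' @param trunk_direction initial (downward) unit growth direction.
#' @param length_decay geometric decay of branch length per generation.
#' @param min_descent minimum downward slope (|dz| per unit arc length) of
#'   ordinary growth, guaranteeing strict descent outside deflections.
#' @param seed integer seed; the generator is a pure function of
#'   (params, seed).
#' @return a `tree_gen_params` list.
#' @export
tree_gen_params <- function(generations = 10L,
                            branch_length_mm = c(20, 2.5),
                            branching_angle_deg = c(30, 8),
                            upward_turn_rate = 0.3,
                            node_spacing_mm = 0.35,
                            trunk_direction = c(0, 0, -1),
                            length_decay = 0.8,
                            min_descent = 0.2,
                            seed = 1L) {
  stopifnot(generations >= 1, node_spacing_mm > 0, upward_turn_rate >= 0,
            branch_length_mm[1] > 0, length_decay > 0, min_descent > 0)
  structure(list(generations = as.integer(generations),
                 branch_length_mm = branch_length_mm,
                 branching_angle_deg = branching_angle_deg,
                 upward_turn_rate = upward_turn_rate,
                 node_spacing_mm = node_spacing_mm,
                 trunk_direction = trunk_direction / sqrt(sum(trunk_direction^2)),
                 length_decay = length_decay,
                 min_descent = min_descent,
                 seed = as.integer(seed)),
            class = "tree_gen_params")
}

# uniform scaling about the (first) root node
scale_tree <- function(tree, f) {
  nodes <- tree$nodes
  root <- nodes[is.na(nodes$parent), , drop = FALSE][1, ]
  org <- c(root$x, root$y, root$z)
  pos <- sweep(sweep(as.matrix(nodes[, c("x", "y", "z")]), 2, org) * f,
               2, org, "+")
  tree$nodes$x <- pos[, 1]
  tree$nodes$y <- pos[, 2]
  tree$nodes$z <- pos[, 3]
  tree$provenance <- c(tree$provenance, sprintf("scale_tree %.17g", f))
  tree
}

# unit vector with z-component clamped to at most -min_descent
clamp_descent <- function(v, min_descent) {
  v <- v / sqrt(sum(v^2))
  if (v[3] > -min_descent) {
    xy <- v[1:2]
    nxy <- sqrt(sum(xy^2))
    if (nxy < 1e-12) xy <- c(1, 0) else xy <- xy / nxy
    v <- c(xy * sqrt(1 - min_descent^2), -min_descent)
  }
  v
}

# orthonormal pair perpendicular to unit vector d
perp_frame <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Generate a synthetic airway tree
#'
#' Grows a seeded random dichotomous tree per [tree_gen_params()]. The
#' returned `airway_tree` has generation labels and an `event_log` attribute
#' recording ground truth: total branch and bifurcation counts, the number
#' of inserted upward deflections, per-generation node counts and the node
#' spacing. The same seed reproduces the tree bit-for-bit.
#'
#' @param params a `tree_gen_params`.
#' @return an `airway_tree` with attribute `event_log`.
#' @export
generate_airway_tree <- function(params) {
  stopifnot(inherits(params, "tree_gen_params"))
  p <- params
  with_seed(p$seed, {
    sp <- p$node_spacing_mm
    ids <- list(); xs <- list(); ys <- list(); zs <- list()
    parents <- list(); gens <- list()
    nseg <- 0L
    add <- function(id, pos, parent, gen) {
      nseg <<- nseg + 1L
      ids[[nseg]] <<- id; xs[[nseg]] <<- pos[, 1]; ys[[nseg]] <<- pos[, 2]
      zs[[nseg]] <<- pos[, 3]; parents[[nseg]] <<- parent
      gens[[nseg]] <<- rep(gen, length(id))
    }
    next_id <- 1L
    root_id <- next_id
    add(root_id, matrix(c(0, 0, 0), 1), NA_integer_, 0L)
    next_id <- next_id + 1L
    turns_inserted <- 0L
    n_branches <- 0L
    n_bifurcations <- 0L

    grow <- function(start_id, start_pos, dir, gen) {
      n_branches <<- n_branches + 1L
      len <- stats::rnorm(1, p$branch_length_mm[1] * p$length_decay^gen,
                          p$branch_length_mm[2] * p$length_decay^gen)
      nsteps <- max(3L, as.integer(round(len / sp)))
      step_dirs <- matrix(dir, nsteps, 3, byrow = TRUE)
      k <- stats::rpois(1, p$upward_turn_rate)
      if (k > 0) {
        turn_len <- 4L
        slots <- if (nsteps - turn_len - 1L >= 2L)
          seq(2L, nsteps - turn_len - 1L, by = turn_len + 3L) else integer(0)
        if (length(slots)) {
          starts <- sort(sample(slots, min(k, length(slots))))
          up <- c(dir[1:2] * 0.4, 0.8)
          up <- up / sqrt(sum(up^2))
          for (s in starts) {
            step_dirs[s:(s + turn_len - 1L), ] <- matrix(up, turn_len, 3,
                                                         byrow = TRUE)
            turns_inserted <<- turns_inserted + 1L
          }
        }
      }
      pos <- sweep(apply(step_dirs * sp, 2, cumsum), 2, start_pos, "+")
      bid <- next_id
      next_id <<- next_id + nsteps
      add(bid:(bid + nsteps - 1L), pos,
          c(start_id, bid:(bid + nsteps - 2L)), gen)
      end_id <- bid + nsteps - 1L
      end_pos <- pos[nsteps, ]
      if (gen + 1L < p$generations) {
        n_bifurcations <<- n_bifurcations + 1L
        fr <- perp_frame(dir)
        phi <- stats::runif(1, 0, 2 * pi)
        for (side in c(0, 1)) {
          th <- abs(stats::rnorm(1, p$branching_angle_deg[1],
                                 p$branching_angle_deg[2])) * pi / 180
          az <- phi + side * (pi + stats::rnorm(1, 0, 0.3))
          child <- cos(th) * dir +
            sin(th) * (cos(az) * fr$e1 + sin(az) * fr$e2)
          child <- clamp_descent(child, p$min_descent)
          grow(end_id, end_pos, child, gen + 1L)
        }
      }
      invisible(NULL)
    }
    grow(root_id, c(0, 0, 0), clamp_descent(p$trunk_direction, p$min_descent),
         0L)

    nodes <- data.frame(id = unlist(ids), x = unlist(xs), y = unlist(ys),
                        z = unlist(zs), parent = unlist(parents),
                        generation = unlist(gens))
    tree <- airway_tree(nodes,
                        provenance = sprintf(
                          "generate_airway_tree seed=%d spacing=%g generations=%d",
                          p$seed, sp, p$generations))
    attr(tree, "event_log") <- list(
      n_branches = n_branches,
      n_bifurcations = n_bifurcations,
      upward_turns = turns_inserted,
      nodes_per_generation = as.integer(table(factor(nodes$generation,
                                                     levels = 0:(p$generations - 1L)))),
      node_spacing_mm = sp,
      seed = p$seed)
    tree
  })
}

#' Parameters for voxel phantoms
#'
#' @param lobe_semiaxes_mm ellipsoid semi-axes of the "lobe" (mm).
#' @param tube_radii_mm radii of the embedded vertical "airway" tubes (mm).
#' @param voxel_spacing_mm isotropic voxel edge (default 0.7, thin-slice CT).
#' @param shell_voxels hollow shell thickness in voxels.
#' @param emphysema_fraction exact fraction of parenchyma voxels assigned
#'   attenuation below -950 HU.
#' @param hollow_sphere_radius_mm if set, generate a plain hollow-sphere
#'   shell of this radius instead of the lobe/airway phantom.
#' @param seed integer seed.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(lobe_semiaxes_mm = c(18, 14, 24),
                           tube_radii_mm = c(2.5, 1.8),
                           voxel_spacing_mm = 0.7,
                           shell_voxels = 1L,
                           emphysema_fraction = 0.08,
                           hollow_sphere_radius_mm = NULL,
                           seed = 1L) {
  stopifnot(all(lobe_semiaxes_mm > 0), voxel_spacing_mm > 0,
            emphysema_fraction >= 0, emphysema_fraction <= 1)
  structure(list(lobe_semiaxes_mm = lobe_semiaxes_mm,
                 tube_radii_mm = tube_radii_mm,
                 voxel_spacing_mm = voxel_spacing_mm,
                 shell_voxels = as.integer(shell_voxels),
                 emphysema_fraction = emphysema_fraction,
                 hollow_sphere_radius_mm = hollow_sphere_radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a hollow lobe/airway voxel phantom
#'
#' Builds a binary `surface_labels` volume containing a hollow ellipsoid
#' shell (the lobe surface) with embedded hollow vertical tubes (airway
#' luminal surfaces), plus a `lumen_mask`, a `lung_mask` (parenchyma) and a
#' synthetic HU volume: parenchyma around -850 HU with an exact configured
#' fraction of blob-shaped emphysema pockets below -950 HU. Ground-truth
#' voxel counts are returned in `$log`. With `hollow_sphere_radius_mm` set,
#' only a spherical shell surface volume is produced (the void-descriptor
#' calibration phantom).
#'
#' @param params a `phantom_params`.
#' @return list with elements `surface`, `lumen_mask`, `lung_mask`, `hu`
#'   (each a `voxel_volume` or NULL) and `log`.
#' @export
generate_lung_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  sp <- p$voxel_spacing_mm
  with_seed(p$seed, {
    if (!is.null(p$hollow_sphere_radius_mm)) {
      # R is the cavity (inner-surface) radius: the void's death radius
      R <- p$hollow_sphere_radius_mm
      half <- R + (p$shell_voxels + 2) * sp
      nx <- as.integer(ceiling(2 * half / sp)) + 1L
      ax <- (seq_len(nx) - 1) * sp - half
      D <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
      shell <- (D >= R & D < R + p$shell_voxels * sp) * 1
      vol <- voxel_volume(shell, spacing = sp, kind = "surface_labels")
      return(list(surface = vol, lumen_mask = NULL, lung_mask = NULL,
                  hu = NULL,
                  log = list(n_surface = sum(shell), radius_mm = R)))
    }
    ax <- p$lobe_semiaxes_mm
    half <- ax + 2 * sp
    dims <- as.integer(ceiling(2 * half / sp)) + 1L
    cx <- lapply(1:3, function(i) (seq_len(dims[i]) - 1) * sp - half[i])
    E <- sqrt(outer(outer((cx[[1]] / ax[1])^2, (cx[[2]] / ax[2])^2, "+"),
                    (cx[[3]] / ax[3])^2, "+"))
    shell_rel <- p$shell_voxels * sp / min(ax)
    shell <- E <= 1 & E > 1 - shell_rel
    interior <- E <= 1 - shell_rel

    lumen <- array(FALSE, dims)
    tube_surf <- array(FALSE, dims)
    ntube <- length(p$tube_radii_mm)
    offs <- if (ntube > 0)
      seq(-ax[1] * 0.4, ax[1] * 0.4, length.out = max(ntube, 2))[seq_len(ntube)]
    else numeric(0)
    zmask <- abs(cx[[3]]) <= ax[3] * 0.55
    for (k in seq_len(ntube)) {
      r <- p$tube_radii_mm[k]
      if (abs(offs[k]) + r + 2 * sp >= ax[1] * sqrt(1 - 0.55^2))
        stop("contract violation: tube exceeds the lobe interior")
      d2 <- sqrt(outer((cx[[1]] - offs[k])^2, cx[[2]]^2, "+"))
      lum2 <- d2 < r
      srf2 <- d2 >= r & d2 < r + 1.5 * sp
      lumen <- lumen | (array(lum2, dims) &
                          rep(zmask, each = dims[1] * dims[2]) |> array(dims))
      tube_surf <- tube_surf | (array(srf2, dims) &
                                  rep(zmask, each = dims[1] * dims[2]) |> array(dims))
    }
    lumen <- lumen & interior
    tube_surf <- tube_surf & interior
    parenchyma <- interior & !lumen & !tube_surf

    hu <- array(40, dims)  # soft tissue outside the lung
    n_par <- sum(parenchyma)
    base <- pmax(stats::rnorm(n_par, -850, 25), -940)
    hu[parenchyma] <- base
    hu[lumen] <- -1000
    m <- round(p$emphysema_fraction * n_par)
    if (m > 0) {
      pidx <- which(parenchyma, arr.ind = TRUE)
      ncent <- max(1L, as.integer(round(m / 4000)))
      cent <- pidx[sample(nrow(pidx), ncent), , drop = FALSE]
      dmin <- rep(Inf, nrow(pidx))
      for (j in seq_len(ncent)) {
        d <- (pidx[, 1] - cent[j, 1])^2 + (pidx[, 2] - cent[j, 2])^2 +
          (pidx[, 3] - cent[j, 3])^2
        dmin <- pmin(dmin, d)
      }
      pick <- order(dmin)[seq_len(m)]
      sel <- which(parenchyma)[pick]
      hu[sel] <- stats::runif(m, -1000, -955)
    }

    list(surface = voxel_volume((shell | tube_surf) * 1, spacing = sp,
                                kind = "surface_labels"),
         lumen_mask = voxel_volume(lumen * 1, spacing = sp,
                                   kind = "lumen_mask"),
         lung_mask = voxel_volume(parenchyma * 1, spacing = sp,
                                  kind = "lung_mask"),
         hu = voxel_volume(hu, spacing = sp, kind = "hu_attenuation"),
         log = list(n_lumen = sum(lumen), n_lung = n_par,
                    n_emphysema = m,
                    emphysema_fraction = if (n_par) m / n_par else 0,
                    n_surface = sum(shell | tube_surf)))
  })
}

#' Expiratory transform of an inspiratory tree
#'
#' Derives an expiratory-phase tree from an inspiratory one by (i) a uniform
#' contraction about the root - the lung shrinks on expiration, which scales
#' the height-barcode depths - and (ii) a branch-crowding ("buckling")
#' transform: each branch segment between consecutive branch points receives
#' a seeded sinusoidal lateral deflection (amplitude `crowding` mm,
#' wavelength `crowding_wavelength` mm, tapered to zero at the segment ends
#' so connectivity geometry is preserved). Buckled branches oscillate toward
#' and away from their neighbours, so neighbouring branches both touch
#' earlier and separate further along the thickening filtration, and the
#' degree-1 branch-to-branch proximity increases by construction. The
#' deflection is horizontal only, leaving node heights untouched. With
#' `contraction = 1` and `crowding = 0` the tree is returned unchanged.
#'
#' @param tree an `airway_tree`.
#' @param contraction uniform scale factor in (0, 1].
#' @param crowding buckling amplitude in mm (0 = none).
#' @param crowding_wavelength buckling wavelength along the branch, mm.
#' @param seed seed for the per-segment buckling phases.
#' @return the transformed `airway_tree`.
#' @export
expiratory_transform <- function(tree, contraction = 0.75, crowding = 3.0,
                                 crowding_wavelength = 10, seed = 1L) {
  stopifnot(contraction > 0, contraction <= 1, crowding >= 0,
            crowding_wavelength > 0)
  nodes <- tree$nodes
  root <- nodes[is.na(nodes$parent), , drop = FALSE][1, ]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  org <- c(root$x, root$y, root$z)
  pos <- sweep(sweep(pos, 2, org) * contraction, 2, org, "+")
  if (crowding > 0 && nrow(nodes) > 1) {
    idx <- match(nodes$parent, nodes$id)
    nkids <- tabulate(idx[!is.na(idx)], nbins = nrow(nodes))
    # maximal non-branching segments: a node opens a segment when it is a
    # root or its parent is a branch point; nodes must follow their parents
    # in row order (true for generated and SWC-written trees)
    seg <- integer(nrow(nodes))
    cur <- 0L
    for (i in seq_len(nrow(nodes))) {
      if (is.na(idx[i]) || idx[i] > i) {
        cur <- cur + 1L
        seg[i] <- cur
      } else if (nkids[idx[i]] >= 2) {
        cur <- cur + 1L
        seg[i] <- cur
      } else seg[i] <- seg[idx[i]]
    }
    with_seed(seed, {
      for (s in unique(seg)) {
        rows <- which(seg == s)
        ph <- stats::runif(1, 0, 2 * pi)  # one draw per segment, always
        if (length(rows) < 4) next
        steps <- sqrt(rowSums((pos[rows[-1], , drop = FALSE] -
                                 pos[rows[-length(rows)], , drop = FALSE])^2))
        arc <- cumsum(c(0, steps))
        d <- pos[rows[length(rows)], ] - pos[rows[1], ]
        d <- d / max(sqrt(sum(d^2)), 1e-9)
        a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        nrm <- a - sum(a * d) * d
        nrm[3] <- 0  # horizontal deflection only
        nn <- sqrt(sum(nrm^2))
        if (nn < 1e-9) next
        nrm <- nrm / nn
        taper <- sin(pi * seq_along(rows) / (length(rows) + 1))
        off <- crowding * sin(2 * pi * arc / crowding_wavelength + ph) * taper
        pos[rows, ] <- pos[rows, ] + outer(off, nrm)
      }
    })
  }
  tree$nodes$x <- pos[, 1]
  tree$nodes$y <- pos[, 2]
  tree$nodes$z <- pos[, 3]
  tree$provenance <- c(tree$provenance,
                       sprintf(
                         "expiratory_transform contraction=%g crowding=%gmm wavelength=%gmm seed=%d",
                         contraction, crowding, crowding_wavelength,
                         as.integer(seed)))
  tree
}

#' Group presets for synthetic cohorts
#'
#' One preset per severity group. Advancing severity is simulated as fewer
#' visible airway generations (airway loss / narrowing below the resolution
#' limit) together with a higher upward-deflection rate per remaining branch
#' (distortion of the bronchial tree) and a larger emphysema fraction. The
#' cohort sampling density is 0.7 mm - the CT voxel size - uniform across
#' all scans, since vertex-count length comparisons require equal sampling.
#'
#' @return named list of per-group parameter lists.
#' @export
cohort_group_presets <- function() {
  list(
    HNS  = list(generations = 7L, upward_turn_rate = 0.30,
                emphysema_fraction = 0.03),
    HS   = list(generations = 6L, upward_turn_rate = 0.40,
                emphysema_fraction = 0.06),
    Mild = list(generations = 5L, upward_turn_rate = 0.55,
                emphysema_fraction = 0.10),
    Mod  = list(generations = 4L, upward_turn_rate = 0.75,
                emphysema_fraction = 0.18))
}

#' Generate a synthetic cohort
#'
#' Writes SWC trees (both phases per participant), optional voxel phantoms
#' (inspiratory only, mirroring that lobe segmentations are typically
#' available for the inspiratory phase), and a metadata manifest CSV with
#' columns participant_id, group, phase, height_m, tree_path, volume_path.
#' Expiratory trees are derived from the inspiratory ones by
#' [expiratory_transform()]. Pure function of (arguments, seed): rerunning
#' with the same seed reproduces every file byte-for-byte.
#'
#' @param dir output directory (created).
#' @param n_per_group named integer vector over groups HNS, HS, Mild, Mod.
#' @param seed master seed.
#' @param presets per-group parameter list, see [cohort_group_presets()].
#' @param node_spacing_mm centerline sampling step for all cohort trees.
#' @param contraction,crowding expiratory transform parameters (a ~25%
#'   height loss on expiration and 3 mm branch buckling by default).
#' @param depth_per_height inspiratory bounding-box depth per metre of body
#'   height (mm/m): each participant's tree is uniformly rescaled about the
#'   root so its depth is `depth_per_height * height_m`, tying airway-tree
#'   size to body height.
#' @param paired fraction of participants receiving an expiratory scan.
#' @param with_volumes also generate per-participant voxel phantoms.
#' @return the manifest data.frame (also written to `<dir>/manifest.csv`).
#' @export
generate_cohort <- function(dir,
                            n_per_group = c(HNS = 4L, HS = 4L, Mild = 4L,
                                            Mod = 4L),
                            seed = 1L,
                            presets = cohort_group_presets(),
                            node_spacing_mm = 0.7,
                            contraction = 0.75,
                            crowding = 3.0,
                            depth_per_height = 42,
                            paired = 1,
                            with_volumes = FALSE) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  if (with_volumes)
    dir.create(file.path(dir, "volumes"), recursive = TRUE,
               showWarnings = FALSE)
  rows <- list()
  i <- 0L
  for (grp in names(n_per_group)) {
    pre <- presets[[grp]]
    if (is.null(pre)) stop("no preset for group ", grp)
    for (k in seq_len(n_per_group[[grp]])) {
      i <- i + 1L
      pid <- sprintf("%s%02d", grp, k)
      pseed <- derive_seed(seed, i)
      height <- with_seed(derive_seed(pseed, 1),
                          round(min(max(stats::rnorm(1, 1.70, 0.08), 1.50),
                                    1.95), 3))
      params <- tree_gen_params(generations = pre$generations,
                                upward_turn_rate = pre$upward_turn_rate,
                                node_spacing_mm = node_spacing_mm,
                                seed = derive_seed(pseed, 2))
      insp <- generate_airway_tree(params)
      depth <- max(insp$nodes$z) - min(insp$nodes$z)
      if (depth > 0)
        insp <- scale_tree(insp, depth_per_height * height / depth)
      tp_in <- file.path("trees", paste0(pid, "_insp.swc"))
      write_tree(insp, file.path(dir, tp_in))
      vol_in <- NA_character_
      if (with_volumes) {
        ph <- generate_lung_phantom(phantom_params(
          emphysema_fraction = pre$emphysema_fraction,
          seed = derive_seed(pseed, 3)))
        vol_in <- file.path("volumes", paste0(pid, "_insp_surface.nii"))
        write_volume(ph$surface, file.path(dir, vol_in))
        write_volume(ph$hu, file.path(dir, sub("_surface", "_hu", vol_in)))
        write_volume(ph$lung_mask,
                     file.path(dir, sub("_surface", "_lungmask", vol_in)))
        write_volume(ph$lumen_mask,
                     file.path(dir, sub("_surface", "_lumen", vol_in)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = grp, phase = "inspiratory",
        height_m = height, tree_path = tp_in, volume_path = vol_in)
      take_exp <- with_seed(derive_seed(pseed, 4), stats::runif(1)) <= paired
      if (take_exp) {
        expi <- expiratory_transform(insp, contraction = contraction,
                                     crowding = crowding,
                                     seed = derive_seed(pseed, 5))
        tp_ex <- file.path("trees", paste0(pid, "_exp.swc"))
        write_tree(expi, file.path(dir, tp_ex))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = grp, phase = "expiratory",
          height_m = height, tree_path = tp_ex, volume_path = NA_character_)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
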