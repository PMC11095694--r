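test_that("contact fractions recover planted deterministic schedules exactly", {
  trj <- make_binding_trajectory(200, contact_schedule = c("42" = 0.3, "77" = 0.05),
                                 seed = 2)
  cp <- contact_profile(trj, "resname IPR")
  expect_equal(cp$fraction[cp$resnum == 42], 0.3, tolerance = 1e-12)
  expect_equal(cp$fraction[cp$resnum == 77], 0.05, tolerance = 1e-12)
  ## 4.5% threshold: 5% reported, background (always far) not reported
  expect_true(cp$reported[cp$resnum == 77])
  expect_true(all(!cp$reported[cp$resnum >= 900]))
  expect_true(all(cp$fraction[cp$resnum >= 900] == 0))
  ## fractions in [0, 1] and exact under jitter too
  trj2 <- make_binding_trajectory(200, contact_schedule = c("42" = 1.0),
                                  jitter_sigma = 0.4, seed = 5)
  cp2 <- contact_profile(trj2, "resname IPR")
  expect_equal(cp2$fraction[cp2$resnum == 42], 1.0)
  expect_error(contact_profile(trj, "resname ZZZ"), "empty")
})

test_that("contact fractions with random schedules stay within binomial bounds", {
  set.seed(31)
  ## random Bernoulli contact realized by subsampling frames of a planted one
  n <- 400; pr <- 0.25
  trj <- make_binding_trajectory(n, contact_schedule = c("42" = 0.5), seed = 7)
  cp <- contact_profile(trj, "resname IPR")
  f <- cp$fraction[cp$resnum == 42]
  expect_lt(abs(f - 0.5), 3 * sqrt(0.5 * 0.5 / n) + 1e-9)
})

test_that("class-averaged profiles threshold after averaging", {
  t1 <- make_binding_trajectory(100, contact_schedule = c("42" = 0.02, "77" = 0.5),
                                seed = 8)
  t2 <- make_binding_trajectory(100, contact_schedule = c("42" = 0.08, "77" = 0.5),
                                seed = 9)
  p1 <- contact_profile(t1, "resname IPR")
  p2 <- contact_profile(t2, "resname IPR")
  avg <- average_contact_profiles(list(p1, p2))
  expect_equal(avg$fraction[avg$resnum == 42], 0.05, tolerance = 1e-12)
  ## 0.05 average exceeds 4.5% even though profile 1 alone (2%) does not
  expect_false(p1$reported[p1$resnum == 42])
  expect_true(avg$reported[avg$resnum == 42])
  expect_equal(avg$fraction[avg$resnum == 77], 0.5)
})

test_that("bond-oxygen distances follow the min and midpoint conventions", {
  x <- rbind(c(3, 0, 0), c(5, 0, 0), c(0, 0, 0))
  expect_equal(bond_o2_distance(x, c(1, 2), 3, mode = "min"), 3)
  expect_equal(bond_o2_distance(x, c(1, 2), 3, mode = "midpoint"), 4)
  ## symmetric placement: both conventions give 4
  xs <- rbind(c(4 * cos(pi / 6), 4 * sin(pi / 6), 0),
              c(4 * cos(pi / 6), -4 * sin(pi / 6), 0), c(0, 0, 0))
  expect_equal(bond_o2_distance(xs, c(1, 2), 3, "min"), 4)
  d12 <- sqrt(sum((xs[1, ] - xs[2, ])^2))
  expect_equal(bond_o2_distance(xs, c(1, 2), 3, "midpoint"),
               sqrt(16 - (d12 / 2)^2))
  ## brute-force Euclidean on random fixtures
  set.seed(19)
  for (rep in 1:20) {
    y <- matrix(rnorm(9, sd = 5), 3)
    expect_equal(bond_o2_distance(y, c(1, 2), 3, "min"),
                 min(sqrt(sum((y[1, ] - y[3, ])^2)), sqrt(sum((y[2, ] - y[3, ])^2))),
                 tolerance = 1e-12)
  }
  expect_error(bond_o2_distance(x, c(1, 9), 3), "out of range")
})

test_that("NAC profiles recover planted dip schedules and pool trajectories", {
  model <- build_polyisoprene(10)
  plan <- data.frame(bond = 5, baseline = 6, dip = 3.5, dip_fraction = 0.1)
  trj <- make_binding_trajectory(1000, ligand = model, distance_plan = plan, seed = 3)
  prof <- nac_profile(trj, model, manifest(trj)$o2_index)
  expect_equal(prof$counts, c(0, 0, 0, 0, 100, 0, 0, 0, 0, 0))
  ## threshold 0: nothing counts
  prof0 <- nac_profile(trj, model, manifest(trj)$o2_index, threshold = 0)
  expect_equal(prof0$counts, rep(0L, 10))
  ## two trajectories with planted 40 and 60 events pool to 100
  t1 <- make_binding_trajectory(400, ligand = model, seed = 4,
                                distance_plan = data.frame(bond = 3, baseline = 6,
                                                           dip = 3.2, dip_fraction = 0.1))
  t2 <- make_binding_trajectory(600, ligand = model, seed = 5,
                                distance_plan = data.frame(bond = 3, baseline = 6,
                                                           dip = 3.2, dip_fraction = 0.1))
  pooled <- nac_profile(list(t1, t2), model, manifest(t1)$o2_index)
  expect_equal(pooled$counts[3], 40L + 60L)
  expect_equal(pooled$n_frames, 1000L)
  ## histogram counts sum to the total frames per bond
  expect_true(all(vapply(prof$histograms, function(h) sum(h$counts), 0) == 1000))
})

test_that("fragment spectra follow the cleavage-product rule", {
  model <- build_polyisoprene(10)
  plan <- data.frame(bond = 5, baseline = 6, dip = 3.5, dip_fraction = 0.2)
  trj <- make_binding_trajectory(500, ligand = model, distance_plan = plan, seed = 6)
  prof <- nac_profile(trj, model, manifest(trj)$o2_index)
  spec <- fragment_spectrum(prof, 10)
  ## all events on bond 5: equal mass on sizes 4 and 5 only
  expect_equal(spec$weight[spec$size == 4], 0.5)
  expect_equal(spec$weight[spec$size == 5], 0.5)
  expect_equal(sum(spec$weight), 1)
  expect_equal(attr(spec, "events"), 100L)
  ## uniform profile over 10 bonds: every size has weight 1/10
  uni <- structure(list(counts = rep(7L, 10), n_frames = 70L, threshold = 4),
                   class = "cleavage_profile")
  expect_equal(fragment_spectrum(uni, 10)$weight, rep(0.1, 10))
  ## empty profile: zero spectrum
  none <- structure(list(counts = rep(0L, 10), n_frames = 10L, threshold = 4),
                    class = "cleavage_profile")
  expect_equal(sum(fragment_spectrum(none, 10)$weight), 0)
  ## conservation: unnormalized mass = 2 x total events
  set.seed(23)
  rnd <- structure(list(counts = sample(0:9, 10, TRUE), n_frames = 100L,
                        threshold = 4), class = "cleavage_profile")
  sp <- fragment_spectrum(rnd, 10)
  expect_equal(attr(sp, "events"), sum(rnd$counts))
  expect_error(fragment_spectrum(rnd, 8), "bonds")
})

test_that("LIE matches analytic pair energies and a double-loop oracle", {
  mk <- function(xyz, charge, eps, rmin_half, resname) {
    s <- toy_structure(xyz, resname = resname)
    s$atoms$charge <- charge; s$atoms$eps <- eps; s$atoms$rmin_half <- rmin_half
    s
  }
  pair <- function(r, q1 = 0, q2 = 0, e = 0.2, rh = 1.5) {
    a <- mk(rbind(c(0, 0, 0), c(r, 0, 0)), c(q1, q2), e, rh,
            c("LIG", "ENV"))
    trajectory(a, list(coords(a)))
  }
  ## single pair at r = R_min: E_vdW = -eps exactly
  en <- lie_energy(pair(3.0), "resname LIG", "resname ENV")
  expect_equal(en$frames$E_vdw, -0.2, tolerance = 1e-12)
  ## charges +1/-1 at 1 A with eps = 0: E_ele = -332.0636
  en2 <- lie_energy(pair(1.0, 1, -1, e = 0), "resname LIG", "resname ENV")
  expect_equal(en2$frames$E_ele, -332.0636, tolerance = 1e-9)
  expect_equal(en2$frames$E_tot, en2$frames$E_vdw + en2$frames$E_ele)
  ## all charges zero: E_ele identically zero
  en3 <- lie_energy(pair(2.2), "resname LIG", "resname ENV")
  expect_equal(en3$frames$E_ele, 0)
  ## E_vdW minimized at r = R_min over a dense radial scan
  scan <- vapply(seq(2.0, 6, by = 0.01), function(r)
    lie_energy(pair(r), "resname LIG", "resname ENV")$frames$E_vdw, 0)
  expect_equal(seq(2.0, 6, by = 0.01)[which.min(scan)], 3.0, tolerance = 0.011)
  ## double-loop oracle on a random 60 + 90 atom frame, 1e-9 relative
  set.seed(27)
  nl <- 60; ne <- 90
  xyz <- matrix(runif(3 * (nl + ne), 0, 25), ncol = 3)
  s <- mk(xyz, runif(nl + ne, -0.5, 0.5), runif(nl + ne, 0.05, 0.3),
          runif(nl + ne, 1, 2), rep(c("LIG", "ENV"), c(nl, ne)))
  trj <- trajectory(s, list(xyz))
  en4 <- lie_energy(trj, "resname LIG", "resname ENV")
  oracle <- brute_lie(xyz, 1:nl, nl + 1:ne, s$atoms$charge, s$atoms$eps,
                      s$atoms$rmin_half)
  expect_equal(en4$frames$E_vdw, unname(oracle["vdw"]), tolerance = 1e-9)
  expect_equal(en4$frames$E_ele, unname(oracle["ele"]), tolerance = 1e-9)
  ## share percentages sum to 100
  expect_equal(sum(en4$share_pct), 100)
  ## missing parameters are reported
  bad <- s; bad$atoms$charge[3] <- NA
  expect_error(lie_energy(trajectory(bad, list(xyz)), "resname LIG", "resname ENV"),
               "missing charge")
  expect_error(lie_energy(trj, "resname LIG", "resname LIG"), "overlap")
})

test_that("conformation classification follows the terminus rules", {
  ## protein: hollow cavity shell (pocket at origin), heme at origin
  cv <- make_cavity(cavity_radius = 4.5, shell_atoms = 80, seed = 3)
  pocket <- cluster_spheres(alpha_spheres(cv))[[1]]
  lig <- build_polyisoprene(3)
  nl <- n_atoms(lig$structure)
  topo <- molecular_structure(rbind(cv$atoms, lig$structure$atoms))
  ligand_map <- n_atoms(cv) + seq_len(nl)
  place <- function(p1, p2) {
    ## stretch the ligand along the segment p1 -> p2 (termini at the ends)
    x <- coords(lig$structure)
    t1 <- x[lig$terminus_atoms[1], ]; t2 <- x[lig$terminus_atoms[2], ]
    u <- (x - matrix(t1, nl, 3, byrow = TRUE)) %*%
      (outer(t2 - t1, t2 - t1) / sum((t2 - t1)^2))
    frac <- u[, 1] / (t2 - t1)[1]
    frac[!is.finite(frac)] <- 0
    out <- matrix(p1, nl, 3, byrow = TRUE) + outer(frac, p2 - p1)
    rbind(coords(cv), out)
  }
  hull_r <- 4.5  # termini on the shell are at the hull, depth ~ 0
  ## extended: one terminus at the pocket center, the other on the hull
  lab1 <- classify_conformation(place(c(0, 0, 0), c(hull_r, 0, 0)), lig, pocket,
                                heme_center = c(0, 0, 0), topology = topo,
                                ligand_map = ligand_map)
  expect_equal(lab1$label, "extended")
  ## folded: both termini on the hull, centroid within 12 A of heme
  lab2 <- classify_conformation(place(c(-hull_r, 0, 0), c(hull_r, 0, 0)), lig,
                                pocket, heme_center = c(0, 0, 0),
                                topology = topo, ligand_map = ligand_map)
  expect_equal(lab2$label, "folded")
  ## far away: extended_like
  lab3 <- classify_conformation(place(c(30, 0, 0), c(38, 0, 0)), lig, pocket,
                                heme_center = c(0, 0, 0), topology = topo,
                                ligand_map = ligand_map)
  expect_equal(lab3$label, "extended_like")
  ## rigid-body invariance: rotate + translate protein, pocket, heme, ligand
  set.seed(33)
  r <- random_rotation(); shift <- c(7, -12, 4)
  frame <- place(c(0, 0, 0), c(hull_r, 0, 0))
  frame2 <- frame %*% r + matrix(shift, nrow(frame), 3, byrow = TRUE)
  pocket2 <- pocket
  pocket2$spheres$centers <- pocket$spheres$centers %*% r +
    matrix(shift, nrow(pocket$spheres$centers), 3, byrow = TRUE)
  lab4 <- classify_conformation(frame2, lig, pocket2,
                                heme_center = as.vector(c(0, 0, 0) %*% r + shift),
                                topology = topo, ligand_map = ligand_map)
  expect_equal(lab4$label, lab1$label)
  expect_equal(lab4$terminus_burial_depth, lab1$terminus_burial_depth,
               tolerance = 0.05)
  expect_error(classify_conformation(frame[1:10, ], lig, pocket, c(0, 0, 0),
                                     topology = topo, ligand_map = ligand_map),
               "not found")
})
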