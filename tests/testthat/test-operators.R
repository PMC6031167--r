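test_that("motif sites are found left to right without overlap", {
  hd <- find_motif_sites(hp_sequence("PPHPPHPP"))
  expect_equal(nrow(hd), 1L)
  expect_equal(hd$kind, "helix_down")
  expect_equal(hd$start, 1L)
  expect_equal(hd$span, 8L)

  hu <- find_motif_sites(hp_sequence("HPPHHPPH"))
  expect_equal(hu$kind, "helix_up")

  sh <- find_motif_sites(hp_sequence("HHHH"))
  expect_equal(sh$kind, "sheet")
  expect_equal(sh$span, 4L)

  expect_equal(nrow(find_motif_sites(hp_sequence("HPHP"))), 0L)

  # maximal sheet runs, several sites, no overlaps
  mix <- find_motif_sites(hp_sequence("HHHHPPHPPHPPHPPPP"))
  expect_true(all(diff(mix$start) >= mix$span[-nrow(mix)]))
  expect_equal(mix$kind[1], "sheet")
  expect_equal(mix$span[1], 4L)
})

test_that("helix mutation writes its template onto an open chain and is idempotent", {
  s <- hp_sequence("HPPHPPHPPH")  # helix_down site at residue 2
  sites <- find_motif_sites(s)
  expect_equal(sites$kind[1], "helix_down")
  start <- sites$start[1]
  expect_equal(sites$start[1], 2L)
  straight <- decode_conformation(rep("F", s$length - 1))
  m <- apply_helix(straight, s, sites[1, ])
  expect_true(m$accepted)
  expect_true(m$offspring$valid)
  tpl <- helix_templates("square")$down
  bonds <- start:(start + sites$span[1] - 2)
  expect_equal(m$offspring$moves[bonds],
               tpl[((bonds - start) %% 4) + 1])
  # applying the same operator to the result changes nothing
  m2 <- apply_helix(m$offspring, s, sites[1, ])
  expect_true(m2$accepted)
  expect_identical(m2$offspring$moves, m$offspring$moves)
  expect_equal(m2$delta_energy, 0L)
})

test_that("the helix templates realize the motif's H-H contacts", {
  # downward helix: H [P P H P P H P P] H, H4-H7 come into contact
  s <- hp_sequence("HPPHPPHPPH")
  m <- apply_helix(decode_conformation(rep("F", 9)), s,
                   find_motif_sites(s)[1, ])
  expect_true(m$accepted)
  expect_equal(conformation_energy(m$offspring, s)$energy, -1L)
  # upward helix: P [H P P H H P P H] P, H2-H5 and H6-H9 pair up
  s2 <- hp_sequence("PHPPHHPPHP")
  sites2 <- find_motif_sites(s2)
  expect_equal(sites2$kind[1], "helix_up")
  m2 <- apply_helix(decode_conformation(rep("F", 9)), s2, sites2[1, ])
  expect_true(m2$accepted)
  expect_equal(conformation_energy(m2$offspring, s2)$energy, -2L)
})

test_that("sheet mutation straightens a run and is idempotent on straight chains", {
  s <- hp_sequence("PPHHHHPP")
  sites <- find_motif_sites(s)
  expect_equal(sites$kind[1], "sheet")
  straight <- decode_conformation(rep("F", 7))
  m <- apply_sheet(straight, s, sites[1, ])
  expect_true(m$accepted)
  expect_identical(m$offspring$moves, straight$moves)
  expect_equal(m$delta_energy, 0L)
  # a bent run gets straightened along the entering direction
  bent <- decode_conformation(c("F", "U", "F", "D", "F", "U", "F"))
  mb <- apply_sheet(bent, s, sites[1, ])
  expect_true(mb$accepted)
  bonds <- sites$start[1]:(sites$start[1] + sites$span[1] - 2)
  entering <- mb$offspring$moves[sites$start[1] - 1]
  expect_true(all(mb$offspring$moves[bonds] == entering))
})

test_that("corner move flips a bend into a free diagonal site and rejects collinear triples", {
  s3 <- hp_sequence("HHH")
  bend <- decode_conformation(c("F", "U"))
  m <- corner_move(bend, s3, 2)
  expect_true(m$accepted)
  expect_true(m$offspring$valid)
  # the flip mirrors the bend across the bond diagonal; re-anchoring the
  # moved first bond turns the up-bend into the down-bend
  expect_identical(m$offspring$moves, c("F", "D"))
  straightm <- corner_move(decode_conformation(c("F", "F")), s3, 2)
  expect_false(straightm$accepted)
  expect_identical(straightm$offspring$moves, c("F", "F"))
  expect_error(corner_move(bend, s3, 1), "corner index")
})

test_that("end-residue pulls on a straight chain always succeed", {
  s <- hp_sequence("HHHHHH")
  straight <- decode_conformation(rep("F", 5))
  set.seed(81)
  for (rep in 1:10) {
    m <- pull_move(straight, s, s$length)
    expect_true(m$accepted)
    expect_true(m$offspring$valid)
  }
  expect_error(pull_move(straight, s, 0), "out of range")
})

test_that("accepted mutations always preserve SAW, unit bonds and the anchor", {
  set.seed(91)
  for (lattice in c("square", "tri8")) {
    lat <- lattice_spec(lattice)
    key <- paste(lat$steps[, 1], lat$steps[, 2])
    s <- hp_sequence(random_hp_string(16, p_h = 0.6))
    conf <- guided_conformation(s, lattice)
    for (rep in 1:1000) {
      m <- mutate_conformation(conf, s)
      if (m$accepted) {
        off <- m$offspring
        expect_true(r_is_saw(off$coords))
        d <- diff(off$coords)
        expect_true(all(paste(d[, 1], d[, 2]) %in% key))
        expect_equal(unname(off$coords[1, ]), c(0L, 0L))
        expect_equal(unname(off$coords[2, ]), c(1L, 0L))
        conf <- off  # walk the chain so many shapes are exercised
      }
    }
  }
})

test_that("mutation dispatch respects the motif probability", {
  set.seed(101)
  s_plain <- hp_sequence("HPHPHPHPHP")  # no motif sites
  conf <- guided_conformation(s_plain)
  ops <- vapply(1:50, function(i)
    mutate_conformation(conf, s_plain)$operator_used, character(1))
  expect_true(all(ops %in% c("corner", "pull")))

  s_rich <- hp_sequence("PPHPPHPPHHHHHPPHHPPH")
  conf2 <- guided_conformation(s_rich)
  ops2 <- vapply(1:50, function(i)
    mutate_conformation(conf2, s_rich, motif_prob = 1)$operator_used,
    character(1))
  expect_true(all(ops2 %in% c("helix_down", "helix_up", "sheet")))
})

test_that("mutation is reproducible under a fixed seed", {
  s <- hp_sequence(random_hp_string(14))
  conf <- decode_conformation(rep("F", 13))
  set.seed(7); a <- mutate_conformation(conf, s)
  set.seed(7); b <- mutate_conformation(conf, s)
  expect_identical(a$offspring$moves, b$offspring$moves)
  expect_identical(a$operator_used, b$operator_used)
})

test_that("repeated pull moves carry a straight chain to the exhaustive optimum", {
  set.seed(111)
  for (str in c("HHPHHPHH", "HHHHPPHH")) {
    s <- hp_sequence(str)
    opt <- exhaustive_optimum(s)$best_energy
    conf <- decode_conformation(rep("F", s$length - 1))
    best <- conformation_energy(conf, s)$energy
    en <- best
    for (t in 1:4000) {
      m <- pull_move(conf, s, sample.int(s$length, 1))
      if (m$accepted && m$energy <= en) {  # non-worsening pull walk
        conf <- m$offspring
        en <- m$energy
        best <- min(best, en)
      }
      if (best == opt) break
    }
    expect_equal(best, opt)
  }
})
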