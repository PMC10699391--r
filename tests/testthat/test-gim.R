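test_that("items are placed by correctness and difficulty", {
  bank <- tiny_bank()
  placed <- place_items(c(Q1 = 1L, Q2 = 0L, Q3 = 0L), bank)
  expect_equal(nrow(placed), 3L)
  expect_equal(placed$side,
               c("left_correct", "right_incorrect", "right_incorrect"))
  expect_equal(placed$y, c(-1.5, -0.5, 0.4))
  # all-correct rows land entirely on the left
  all_c <- place_items(setNames(rep(1L, 6L), bank$items$item_id), bank)
  expect_true(all(all_c$side == "left_correct"))
  # uncalibrated items are named in the error
  bank$items$difficulty[2] <- NA
  expect_error(place_items(c(Q2 = 1L), bank), "Q2")
})

test_that("co-location merges by single linkage within each cluster-side cell", {
  cfg <- layout_config(cluster_tolerance = 0.15)
  placed <- data.frame(
    item_id = c("A", "B", "C", "D", "E"),
    subject_cluster = c("DECEL", "DECEL", "DECEL", "PHYS", "PHYS"),
    side = c(rep("right_incorrect", 3L), "left_correct", "left_correct"),
    y = c(1.00, 1.05, 2.0, 1.00, 1.05), stringsAsFactors = FALSE)
  grp <- group_colocated(placed, cfg)
  dec <- grp$groups[grp$groups$subject_cluster == "DECEL", ]
  expect_equal(dec$count, c(2L, 1L))
  expect_equal(dec$label[1], "DECEL (2)")
  expect_equal(dec$y[1], 1.025)
  # equal difficulties never merge across clusters
  expect_equal(sum(grp$groups$subject_cluster == "PHYS"), 1L)

  # chain linking: consecutive gaps under tolerance merge transitively
  # even when the end-to-end span exceeds it (matches a brute-force
  # transitive closure of the pairwise relation)
  chain <- data.frame(item_id = c("X", "Y", "Z"), subject_cluster = "MHR",
                      side = "right_incorrect", y = c(0.0, 0.1, 0.2),
                      stringsAsFactors = FALSE)
  closure <- function(y, tol) {   # oracle: transitive closure
    adj <- abs(outer(y, y, `-`)) <= tol
    reach <- adj
    for (k in seq_along(y)) reach <- reach | (reach %*% reach) > 0
    length(unique(apply(reach, 1L, function(r) paste(which(r), collapse = ""))))
  }
  grp2 <- group_colocated(chain, cfg)
  expect_equal(nrow(grp2$groups), closure(chain$y, 0.15))
  expect_equal(grp2$groups$count, 3L)
  expect_equal(grp2$groups$label, "MHR (3)")

  # zero tolerance degenerates to singletons except exact ties
  tie <- data.frame(item_id = c("U", "V", "W"), subject_cluster = "NORM",
                    side = "left_correct", y = c(0.5, 0.5, 0.7),
                    stringsAsFactors = FALSE)
  grp3 <- group_colocated(tie, layout_config(cluster_tolerance = 0))
  expect_equal(sort(grp3$groups$count), c(1L, 2L))
})

test_that("quadrants partition items around the pass line", {
  bank <- tiny_bank()
  placed <- place_items(setNames(c(1L, 0L, 1L, 0L, 1L, 0L),
                                 bank$items$item_id), bank)
  q <- assign_quadrants(placed, pass_line = 0.4)
  # incorrect below the pass standard -> the priority revision quadrant
  expect_equal(q$quadrant[q$item_id == "Q2"], "lower_right")
  # correct above the pass standard
  expect_equal(q$quadrant[q$item_id == "Q5"], "upper_left")
  # exactly on the line falls below (closed-below convention)
  expect_equal(q$quadrant[q$item_id == "Q3"], "lower_left")
  expect_equal(sum(table(q$quadrant)), nrow(placed))
  expect_error(assign_quadrants(placed, NA), "finite")
})

test_that("clusters are flagged by easy misses and secure hits", {
  cfg <- layout_config()
  mk <- function(cluster, side, y) {
    data.frame(item_id = sprintf("%s%02d", cluster, seq_along(y)),
               subject_cluster = cluster, side = side, y = y,
               stringsAsFactors = FALSE)
  }
  # two incorrect items easier than the candidate -> weakness
  placed <- mk("DECEL", "right_incorrect", c(-0.5, 0.1))
  expect_equal(unname(flag_subjects(placed, 0.8, cfg)["DECEL"]), "weakness")
  # four correct items, one above ability -> strength
  placed <- mk("BFHR", "left_correct", c(-1, -0.5, 0, 1.8))
  expect_equal(unname(flag_subjects(placed, 0.8, cfg)["BFHR"]), "strength")
  # misses only on genuinely hard items -> no flag
  placed <- rbind(mk("RANZ", "left_correct", c(-1, 0)),
                  mk("RANZ", "right_incorrect", c(1.5, 2)))
  expect_equal(unname(flag_subjects(placed, 0.8, cfg)["RANZ"]), "none")
  # weakness beats strength when both rules could fire
  placed <- rbind(mk("MHR", "left_correct", c(-1, -0.5, 1.5)),
                  mk("MHR", "right_incorrect", c(-0.2, 0)))
  expect_equal(unname(flag_subjects(placed, 0.8, cfg)["MHR"]), "weakness")
  # an item exactly at the ability line counts as an easy miss
  placed <- mk("UPFH", "right_incorrect", c(0.8, 0.8))
  expect_equal(unname(flag_subjects(placed, 0.8, cfg)["UPFH"]), "weakness")
})

test_that("build_gim assembles columns, lines and flags deterministically", {
  fx <- make_fsep_fixture(seed = 1)
  g <- build_gim("C0001", fx$responses, fx$bank, pass_line = "75%")
  expect_equal(g$columns, fsep_clusters)
  expect_equal(sum(g$groups$count), 60L)
  expect_equal(sort(unlist(g$group_members)), sort(g$placed$item_id))
  # identical rebuild
  g2 <- build_gim("C0001", fx$responses, fx$bank, pass_line = "75%")
  expect_identical(g, g2)
  # percentage pass line converts through the test characteristic curve
  deltas <- setNames(fx$bank$items$difficulty, fx$bank$items$item_id)
  expect_equal(expected_score(g$pass_line, deltas), 45, tolerance = 1e-6)
  expect_error(build_gim("NOBODY", fx$responses, fx$bank), "NOBODY")
})

test_that("a flawless candidate has an empty right side and no weakness", {
  bank <- tiny_bank()
  g <- build_gim("CAND1", tiny_scores(rep(1L, 6L)), bank, ability = 2)
  expect_true(all(g$placed$side == "left_correct"))
  expect_false(any(g$flags == "weakness"))
  expect_null(g$pass_line)
  expect_true(all(is.na(g$placed$quadrant)))
})

test_that("layout invariants hold across simulated candidates", {
  fx <- make_fsep_fixture(seed = 2, n_persons = 40)
  cal <- calibrate_cml(fx$responses)
  bank <- fx$bank
  bank$items$difficulty <- unname(cal$difficulties[bank$items$item_id])
  bank$calibration_constraint <- "mean_zero"
  pers <- estimate_persons(fx$responses, cal$difficulties)
  pass <- invert_tcc(0.75 * 60, cal$difficulties)
  for (cid in rownames(fx$responses$scores)[1:40]) {
    g <- build_gim(cid, fx$responses, bank, abilities = pers,
                   pass_line = pass)
    # bijection between items and group membership
    expect_equal(sum(g$groups$count), 60L)
    expect_equal(anyDuplicated(unlist(g$group_members)), 0L)
    # side fidelity against the raw scores
    sc <- fx$responses$scores[cid, g$placed$item_id]
    expect_equal(g$placed$side == "left_correct", unname(sc == 1L))
    # group ordering within columns follows difficulty
    for (cl in g$columns) {
      for (sd in c("left_correct", "right_incorrect")) {
        ys <- g$groups$y[g$groups$subject_cluster == cl &
                           g$groups$side == sd]
        expect_true(!is.unsorted(ys))
      }
    }
    # quadrants partition all 60 items
    expect_equal(sum(table(g$placed$quadrant)), 60L)
  }
})
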