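#' Load the task map
#'
#' The map assigns one robot task (name + description) to every
#' combination of the four motor-imagery classes and the three scenes —
#' 12 tasks in total. The bundled default mirrors the published command
#' mapping; an edited JSON with the same schema can be supplied instead.
#'
#' @param path JSON file; `NULL` loads the bundled default.
#' @return a `task_map` with `names` and `descriptions` as 4 x 3 matrices
#'   indexed `[mi, scene]`.
#' @export
task_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "task_map.json", package = "neurointent")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mi <- vapply(raw$mi_classes, identity, "")
  sc <- vapply(raw$scenes, identity, "")
  nm <- matrix(NA_character_, length(mi), length(sc),
               dimnames = list(mi, sc))
  ds <- nm
  for (t in raw$tasks) {
    i <- match(t$mi, mi)
    j <- match(t$scene, sc)
    if (is.na(i) || is.na(j))
      stop("task entry references unknown class/scene: ", t$name)
    if (!is.na(nm[i, j])) stop("duplicate (mi, scene) cell: ", t$name)
    nm[i, j] <- t$name
    ds[i, j] <- t$description
  }
  if (anyNA(nm)) stop("task map does not cover all (mi, scene) pairs")
  if (anyDuplicated(as.vector(nm))) stop("task names are not distinct")
  structure(list(mi_classes = mi, scenes = sc, names = nm,
                 descriptions = ds), class = "task_map")
}

check_prob <- function(p, len, what) {
  if (length(p) != len)
    stop(sprintf("%s must have length %d", what, len))
  if (any(p < 0)) stop(what, " must be non-negative")
  s <- sum(p)
  if (s <= 0) stop(what, " sums to zero")
  if (abs(s - 1) > 1e-6) {
    warning(what, " does not sum to 1; renormalizing")
    p <- p / s
  } else {
    p <- p / s
  }
  p
}

#' Decision-level fusion of motor-imagery and scene posteriors
#'
#' Multiplies the two posterior vectors into a joint 4 x 3 task
#' distribution `P_task(i, j) = P_MI(i) * P_scene(j)` and picks the argmax
#' (ties broken lexicographically: lowest MI index first, then lowest
#' scene index). Because the joint is a product measure, its argmax always
#' coincides with the pair of marginal argmaxes.
#'
#' @param p_mi length-4 motor-imagery posterior.
#' @param p_scene length-3 scene posterior.
#' @param map a [task_map()].
#' @param tau confidence floor: if the winning joint probability is below
#'   `tau` the decision is flagged as rejected (default 0 = never reject).
#' @return a `task_decision` with the joint matrix, indices, task name and
#'   command description.
#' @export
fuse <- function(p_mi, p_scene, map = task_map(), tau = 0) {
  p_mi <- check_prob(as.numeric(p_mi), 4, "p_mi")
  p_scene <- check_prob(as.numeric(p_scene), 3, "p_scene")
  p_task <- outer(p_mi, p_scene)
  dimnames(p_task) <- list(map$mi_classes, map$scenes)
  # row-major scan => lexicographic (mi, scene) tie-breaking
  flat <- as.vector(t(p_task))
  k <- which.max(flat) - 1L
  i <- k %/% 3L + 1L
  j <- k %% 3L + 1L
  structure(list(p_mi = p_mi, p_scene = p_scene, p_task = p_task,
                 mi = i - 1L, scene = j - 1L,
                 mi_class = map$mi_classes[i], scene_name = map$scenes[j],
                 task = map$names[i, j], command = map$descriptions[i, j],
                 accepted = p_task[i, j] >= tau),
            class = "task_decision")
}

#' @export
print.task_decision <- function(x, ...) {
  cat(sprintf("<task_decision> %s (%s x %s, p = %.3f)%s\n  %s\n",
              x$task, x$mi_class, x$scene_name, x$p_task[x$mi + 1, x$scene + 1],
              if (x$accepted) "" else " [REJECTED]", x$command))
  invisible(x)
}

#' Per-task accuracy table
#'
#' @param predicted character vector of predicted task names.
#' @param truth character vector of true task names, same length.
#' @param map a [task_map()] defining the 12-task label set.
#' @return data.frame with one row per task (accuracy in percent, `NA`
#'   when a task has no ground-truth examples) plus a macro-average row
#'   over the represented tasks.
#' @export
evaluate_tasks <- function(predicted, truth, map = task_map()) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  all_tasks <- as.vector(map$names)
  bad <- setdiff(unique(c(predicted, truth)), all_tasks)
  if (length(bad) > 0)
    stop("labels outside the task set: ", paste(bad, collapse = ", "))
  acc <- vapply(all_tasks, function(t) {
    n <- sum(truth == t)
    if (n == 0) return(NA_real_)
    100 * sum(predicted == t & truth == t) / n
  }, 0)
  out <- data.frame(task = all_tasks,
                    scene = rep(map$scenes, each = length(map$mi_classes)),
                    mi = rep(map$mi_classes, times = length(map$scenes)),
                    accuracy = acc, row.names = NULL)
  rbind(out, data.frame(task = "Average", scene = "-", mi = "-",
                        accuracy = mean(acc, na.rm = TRUE)))
}
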