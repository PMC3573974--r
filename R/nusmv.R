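# Export to the NuSMV input language.
#
# The encoding follows the standard asynchronous idiom: one ranged variable
# per node, a free control variable `ctrl` naming the node allowed to update
# at each instant (every other variable holds), one FAIRNESS constraint per
# ctrl value so no node is starved forever, and CTL SPEC lines for the
# properties.  All weighted sums are emitted on a x3 integer scale so that
# 1/3 weights stay exact; the level-1 and level-2 entry comparisons become
# `>= 2` and `>= 5` (0.5*3 and 1.5*3 rounded up to the next integer, valid
# because scaled sums are integral).  Running NuSMV is optional
# cross-validation, not a dependency of any analysis in this package.

scale3 <- function(w6) {
  stopifnot(w6 %% 2 == 0)
  w6 %/% 2L
}

# integer bound b such that (sum3 >= b) <=> (sum >= th) for integral sum3
ge_bound3 <- function(th6) as.integer(ceiling(th6 * 3 / 6))

smv_sum_expr <- function(model, node) {
  int <- model$internal
  i <- match(node, model$nodes$name)
  w <- int$W6[i, ]
  terms <- character(0)
  for (j in which(w != 0L)) {
    c3 <- scale3(w[j])
    terms <- c(terms, sprintf("%s%d * %s",
                              if (c3 >= 0 && length(terms) > 0) "+ " else
                                if (c3 < 0) "- " else "",
                              abs(c3), model$nodes$name[j]))
  }
  if (length(terms) == 0) "0" else paste(terms, collapse = " ")
}

smv_update_expr <- function(model, node) {
  int <- model$internal
  i <- match(node, model$nodes$name)
  maxl <- int$maxlev[i]
  sum_name <- paste0("sum_", node)
  if (model$semantics == "li_binary") {
    decay <- if (model$nodes$self_degrading[i]) {
      sprintf("        %s = 0 : 0;\n", sum_name)
    } else ""
    sprintf(paste0("      case\n",
                   "        %s > 0 : 1;\n",
                   "        %s < 0 : 0;\n", decay,
                   "        TRUE : %s;\n",
                   "      esac"),
            sum_name, sum_name, node)
  } else {
    th <- int$th6[i, ]
    lines <- character(0)
    for (s in 0:maxl) {
      if (s < maxl) {
        up <- ge_bound3(th[s + 1])
        lines <- c(lines, sprintf("        %s = %d & %s >= %d : %d;",
                                  node, s, sum_name, up, s + 1L))
      }
      if (s > 0) {
        dn <- ge_bound3(th[s])
        lines <- c(lines, sprintf("        %s = %d & %s < %d : %d;",
                                  node, s, sum_name, dn, s - 1L))
      }
    }
    paste0("      case\n", paste(lines, collapse = "\n"),
           sprintf("\n        TRUE : %s;\n      esac", node))
  }
}

smv_cond <- function(cond, model) {
  if (cond$kind == "level") {
    sprintf("%s >= %d", cond$node, cond$level)
  } else {
    paste(sprintf("%s = %d", names(cond$state), cond$state),
          collapse = " & ")
  }
}

#' Export a model and properties to NuSMV
#'
#' Emits a syntactically complete SMV module: ranged node variables, a
#' non-deterministic control variable selecting the node to update, update
#' rules guarded by the control variable, one FAIRNESS constraint per node,
#' and one SPEC line per property (precedence as a safety formula over a
#' latched monitor variable; response and global-attractor properties as
#' AF formulas evaluated under the fairness constraints).
#'
#' @param model A `ccn_model`.
#' @param initial Initial state; defaults to the model's stimulated G1.
#' @param properties List of `ccn_property`; defaults to
#'   [default_property_set()].
#' @param path Optional output file; when NULL the SMV text is returned.
#' @return Character scalar of SMV source (invisibly when `path` is given).
#' @examples
#' txt <- export_nusmv(yeast_model("proposed"))
#' cat(substr(txt, 1, 300))
#' @export
export_nusmv <- function(model, initial = stimulated_g1(model),
                         properties = default_property_set(model),
                         path = NULL) {
  initial <- validate_state_vec(initial, model$nodes, "initial")
  nn <- model$nodes$name
  int <- model$internal
  out <- c(sprintf("-- model '%s' (%s semantics), sums on a x3 integer scale",
                   model$name, model$semantics),
           "MODULE main", "VAR")
  for (i in seq_along(nn)) {
    out <- c(out, sprintf("  %s : 0..%d;", nn[i], int$maxlev[i]))
  }
  out <- c(out, sprintf("  ctrl : {%s};", paste0("c_", nn, collapse = ", ")))
  # monitors for precedence properties
  prec <- Filter(function(p) p$type == "precedence", properties)
  for (p in prec) {
    out <- c(out, sprintf("  seen_%s : boolean;", p$name))
  }
  out <- c(out, "DEFINE")
  for (node in nn) {
    out <- c(out, sprintf("  sum_%s := %s;", node, smv_sum_expr(model, node)))
  }
  out <- c(out, "ASSIGN")
  for (i in seq_along(nn)) {
    out <- c(out, sprintf("  init(%s) := %d;", nn[i], initial[i]))
    out <- c(out, sprintf("  next(%s) :=", nn[i]),
             "    case",
             sprintf("      ctrl = c_%s :", nn[i]),
             smv_update_expr(model, nn[i]), ";",
             sprintf("      TRUE : %s;", nn[i]),
             "    esac;")
  }
  for (p in prec) {
    ant <- smv_cond(p$antecedent, model)
    out <- c(out,
             sprintf("  init(seen_%s) := %s;", p$name, ant),
             sprintf("  next(seen_%s) := seen_%s | next(%s);",
                     p$name, p$name, ant))
  }
  for (node in nn) {
    out <- c(out, sprintf("FAIRNESS ctrl = c_%s", node))
  }
  for (p in properties) {
    line <- switch(p$type,
      precedence = sprintf("SPEC AG ((%s) -> seen_%s)",
                           smv_cond(p$consequent, model), p$name),
      response = sprintf("SPEC AG ((%s) -> AF (%s))",
                         smv_cond(p$trigger, model),
                         smv_cond(p$obligation, model)),
      global_attractor = sprintf("SPEC AF (%s)",
                                 smv_cond(p$target, model)))
    out <- c(out, paste0("-- property ", p$name), line)
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
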