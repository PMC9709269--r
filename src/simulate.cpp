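#include <Rcpp.h>
using namespace Rcpp;

// Compiled trial loop. Semantics mirror the R reference engine
// (step_trial / select_operator / learn_update) exactly, including the
// order in which random numbers are consumed: one logistic draw per
// candidate operator per selection event (in operator order), plus one
// uniform draw only on an exact score tie. This makes a run bit-identical
// between the R and compiled backends under the same seed.
//
// Encoding (see encode_operators() on the R side):
//   symbols: 0 = nil, 1..n_sym = symbol ids (forms first)
//   slots:   0..2 V1-V3, 3..7 WM1-WM5, 8..11 RT1-RT4, 12 AC1
//   prim rows (kind, a, b):
//     1 cmp_eq(slot a, slot b)   2 cmp_ne(slot a, slot b)
//     3 is_nil(slot a)           4 not_nil(slot a)
//     5 copy(slot a -> slot b)   6 set_const(sym a -> slot b)
//     7 ext_action(sym a)

static const int SLOT_V1 = 0, SLOT_WM1 = 3, SLOT_RT1 = 8, SLOT_AC1 = 12;

struct OpSet {
  std::vector<IntegerMatrix> cond;
  std::vector<IntegerMatrix> act;
  int n;
};

static bool conditions_hold(const IntegerMatrix& cm, const int* buf) {
  for (int r = 0; r < cm.nrow(); ++r) {
    int kind = cm(r, 0), a = cm(r, 1), b = cm(r, 2);
    switch (kind) {
    // content comparisons require content: an empty slot (0) is neither
    // equal nor unequal to anything
    case 1: if (buf[a] == 0 || buf[a] != buf[b]) return false; break;
    case 2: if (buf[a] == 0 || buf[b] == 0 || buf[a] == buf[b]) return false; break;
    case 3: if (buf[a] != 0) return false; break;
    case 4: if (buf[a] == 0) return false; break;
    default: stop("bad condition prim kind");
    }
  }
  return true;
}

// returns chunk row or -1; stops on ambiguity
static int retrieve_row(const IntegerMatrix& lex, const int* rt,
                        const std::vector<int>& form2row) {
  // fast path: a form constraint identifies the chunk directly
  if (rt[1] != 0) {
    int row = form2row[rt[1]];
    if (row < 0) return -1;
    if ((rt[0] != 0 && lex(row, 0) != rt[0]) ||
        (rt[2] != 0 && lex(row, 2) != rt[2]) ||
        (rt[3] != 0 && lex(row, 3) != rt[3])) return -1;
    return row;
  }
  int hit = -1;
  for (int i = 0; i < lex.nrow(); ++i) {
    if ((rt[0] != 0 && lex(i, 0) != rt[0]) ||
        (rt[2] != 0 && lex(i, 2) != rt[2]) ||
        (rt[3] != 0 && lex(i, 3) != rt[3])) continue;
    if (hit >= 0) stop("ambiguous retrieval: lexicon must be unambiguous");
    hit = i;
  }
  return hit;
}

// [[Rcpp::export]]
List run_items_cpp(IntegerMatrix items, IntegerVector order, List op_cond,
                   List op_act, IntegerMatrix lexicon, int pronoun_form,
                   NumericMatrix strengths, double alpha, double reward,
                   double scale, bool learn, bool log_fired) {
  const int n_ops = op_cond.size();
  OpSet ops;
  ops.n = n_ops;
  for (int j = 0; j < n_ops; ++j) {
    ops.cond.push_back(as<IntegerMatrix>(op_cond[j]));
    ops.act.push_back(as<IntegerMatrix>(op_act[j]));
  }
  const int n_sym = strengths.nrow();
  std::vector<int> form2row(n_sym + 1, -1);
  for (int i = 0; i < lexicon.nrow(); ++i) form2row[lexicon(i, 1)] = i;

  const int n_trials = order.size();
  IntegerMatrix rec(n_trials, 5); // item_row, pred_role, pred_form, rewarded, n_fired
  std::vector<int> fired_log;
  std::vector<double> noise(n_ops), score(n_ops);
  std::vector<int> fired;
  fired.reserve(16);

  for (int t = 0; t < n_trials; ++t) {
    int row = order[t] - 1;
    int subj = items(row, 0), verb = items(row, 1), obj = items(row, 2);
    int cont_token = items(row, 3), cont_ref = items(row, 4);

    int buf[13];
    std::fill(buf, buf + 13, 0);
    buf[SLOT_V1] = subj; buf[SLOT_V1 + 1] = verb; buf[SLOT_V1 + 2] = obj;

    fired.clear();
    int pred_role = 0, pred_form = 0, rewarded = -1;
    bool observed = false, done = false;

    while (!done) {
      // score every candidate: activation over WM1-WM3 context + noise
      for (int j = 0; j < n_ops; ++j) noise[j] = R::rlogis(0.0, scale);
      for (int j = 0; j < n_ops; ++j) {
        double act = 0.0;
        for (int c = SLOT_WM1; c < SLOT_WM1 + 3; ++c) {
          int s = buf[c];
          if (s != 0) act += strengths(s - 1, j);
        }
        score[j] = act + noise[j];
      }
      int best = -1;
      double best_score = 0.0;
      int n_tied = 0;
      for (int j = 0; j < n_ops; ++j) {
        if (!conditions_hold(ops.cond[j], buf)) continue;
        if (best < 0 || score[j] > best_score) {
          best = j; best_score = score[j]; n_tied = 1;
        } else if (score[j] == best_score) {
          ++n_tied;
        }
      }
      if (best < 0) { done = true; break; }
      if (n_tied > 1) {
        int pick = (int)std::floor(unif_rand() * n_tied);
        int seen = 0;
        for (int j = 0; j < n_ops; ++j) {
          if (!conditions_hold(ops.cond[j], buf)) continue;
          if (score[j] == best_score && seen++ == pick) { best = j; break; }
        }
      }

      // fire
      const IntegerMatrix& am = ops.act[best];
      bool request = false, consumed = false, readnext = false;
      for (int r = 0; r < am.nrow(); ++r) {
        int kind = am(r, 0), a = am(r, 1), b = am(r, 2);
        if (kind == 5) {
          if (buf[a] == 0) stop("operator copies from empty slot (operator-design bug)");
          buf[b] = buf[a];
          if (a >= SLOT_RT1 && a < SLOT_AC1 && b >= SLOT_WM1 && b < SLOT_RT1)
            consumed = true;
          if (b >= SLOT_RT1 && b < SLOT_AC1) request = true;
        } else if (kind == 6) {
          buf[b] = a;
          if (b >= SLOT_RT1 && b < SLOT_AC1) request = true;
        } else if (kind == 7) {
          readnext = true; // the only external action in this model
        } else {
          stop("bad action prim kind");
        }
      }
      fired.push_back(best);

      if (request) {
        int hit = retrieve_row(lexicon, buf + SLOT_RT1, form2row);
        if (hit < 0) stop("retrieval failure: no chunk matches request");
        for (int k = 0; k < 4; ++k) buf[SLOT_RT1 + k] = lexicon(hit, k);
      }
      if (consumed) {
        for (int k = 0; k < 4; ++k) buf[SLOT_RT1 + k] = 0;
      }
      if (readnext) {
        pred_role = (buf[SLOT_WM1 + 4] == buf[SLOT_WM1]) ? 1 : 2;
        pred_form = (buf[SLOT_WM1 + 3] == pronoun_form) ? 2 : 1;
        if (cont_token == 0) {
          done = true; // evaluation-only item: prediction is the outcome
        } else {
          buf[SLOT_V1] = cont_token; buf[SLOT_V1 + 1] = cont_ref;
          buf[SLOT_V1 + 2] = 0; buf[SLOT_AC1] = 0;
          observed = true;
          rewarded = (buf[SLOT_WM1 + 3] == cont_token &&
                      buf[SLOT_WM1 + 4] == cont_ref) ? 1 : 0;
        }
      }
    }

    if (learn && observed) {
      double target = (rewarded == 1) ? reward : 0.0;
      int ctx[3] = {subj, verb, obj};
      for (size_t f = 0; f < fired.size(); ++f) {
        bool dup = false;
        for (size_t g = 0; g < f; ++g) if (fired[g] == fired[f]) { dup = true; break; }
        if (dup) continue;
        int j = fired[f];
        for (int c = 0; c < 3; ++c) {
          if (ctx[c] == 0) continue;
          double s = strengths(ctx[c] - 1, j);
          strengths(ctx[c] - 1, j) = s + alpha * (target - s);
        }
      }
    }

    rec(t, 0) = row + 1;
    rec(t, 1) = pred_role;
    rec(t, 2) = pred_form;
    rec(t, 3) = rewarded;
    rec(t, 4) = (int)fired.size();
    if (log_fired) {
      for (size_t f = 0; f < fired.size(); ++f) fired_log.push_back(fired[f] + 1);
    }
  }

  List out = List::create(
    _["records"] = rec,
    _["strengths"] = strengths
  );
  if (log_fired) out["fired"] = wrap(fired_log);
  return out;
}
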