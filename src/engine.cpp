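#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stack-machine opcodes for compiled update rules. Each rule is a postfix
// program over vectors of length n_sites; the R side (.compile_rule) emits
// the programs and guarantees well-formedness.
enum Op {
  OP_PUSH = 1,   // push constant (xarg)
  OP_CUR = 2,    // push current-day value of variable iarg
  OP_LAG = 3,    // push previous-day value of variable iarg
  OP_DRV = 4,    // push today's value of driver iarg
  OP_ADD = 10, OP_SUB = 11, OP_MUL = 12, OP_DIV = 13, OP_POW = 14,
  OP_NEG = 15,
  OP_LT = 20, OP_LE = 21, OP_GT = 22, OP_GE = 23, OP_EQ = 24, OP_NE = 25,
  OP_AND = 26, OP_OR = 27, OP_NOT = 28,
  OP_PMIN = 30, OP_PMAX = 31, OP_IFELSE = 32,
  OP_EXP = 40, OP_LOG = 41, OP_SQRT = 42, OP_ABS = 43
};

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List drv, IntegerVector op, IntegerVector iarg,
                NumericVector xarg, IntegerVector rule_start,
                IntegerVector rule_len, IntegerVector eval_order,
                NumericVector init, LogicalVector repl, NumericVector cst,
                int n_days, int n_sites, int max_depth) {
  const int n_vars = eval_order.size();
  std::vector<const double*> drvp(drv.size());
  for (int i = 0; i < drv.size(); ++i) {
    drvp[i] = REAL((SEXP)drv[i]);
  }
  List out(n_vars);
  std::vector<double*> outp(n_vars);
  for (int v = 0; v < n_vars; ++v) {
    NumericMatrix m(n_days, n_sites);
    out[v] = m;
    outp[v] = REAL((SEXP)out[v]);
  }
  std::vector<double> cur(n_vars * n_sites), prev(n_vars * n_sites);
  for (int v = 0; v < n_vars; ++v) {
    for (int s = 0; s < n_sites; ++s) prev[v * n_sites + s] = init[v];
  }
  std::vector<double> stack((size_t)(max_depth + 1) * n_sites);

  for (int day = 0; day < n_days; ++day) {
    for (int k = 0; k < n_vars; ++k) {
      const int v = eval_order[k] - 1;  // 0-based variable slot
      double* res = &cur[v * n_sites];
      if (repl[v]) {
        for (int s = 0; s < n_sites; ++s) res[s] = cst[v];
      } else {
        int sp = -1;  // top-of-stack index (in units of n_sites blocks)
        const int p0 = rule_start[v] - 1;
        const int pn = rule_len[v];
        for (int p = p0; p < p0 + pn; ++p) {
          double* top;
          switch (op[p]) {
          case OP_PUSH:
            top = &stack[(size_t)(++sp) * n_sites];
            for (int s = 0; s < n_sites; ++s) top[s] = xarg[p];
            break;
          case OP_CUR: {
            const double* src = &cur[(size_t)(iarg[p] - 1) * n_sites];
            top = &stack[(size_t)(++sp) * n_sites];
            for (int s = 0; s < n_sites; ++s) top[s] = src[s];
            break; }
          case OP_LAG: {
            const double* src = &prev[(size_t)(iarg[p] - 1) * n_sites];
            top = &stack[(size_t)(++sp) * n_sites];
            for (int s = 0; s < n_sites; ++s) top[s] = src[s];
            break; }
          case OP_DRV: {
            const double* src = drvp[iarg[p] - 1] + (size_t)day;
            top = &stack[(size_t)(++sp) * n_sites];
            // driver matrices are n_days x n_sites, column-major
            for (int s = 0; s < n_sites; ++s) top[s] = src[(size_t)s * n_days];
            break; }
          case OP_NEG: {
            top = &stack[(size_t)sp * n_sites];
            for (int s = 0; s < n_sites; ++s) top[s] = -top[s];
            break; }
          case OP_NOT: {
            top = &stack[(size_t)sp * n_sites];
            for (int s = 0; s < n_sites; ++s) {
              top[s] = std::isnan(top[s]) ? NA_REAL : (top[s] == 0.0 ? 1.0 : 0.0);
            }
            break; }
          case OP_EXP: case OP_LOG: case OP_SQRT: case OP_ABS: {
            top = &stack[(size_t)sp * n_sites];
            for (int s = 0; s < n_sites; ++s) {
              switch (op[p]) {
              case OP_EXP: top[s] = std::exp(top[s]); break;
              case OP_LOG: top[s] = std::log(top[s]); break;
              case OP_SQRT: top[s] = std::sqrt(top[s]); break;
              default: top[s] = std::fabs(top[s]);
              }
            }
            break; }
          case OP_IFELSE: {
            double* c = &stack[(size_t)(sp - 2) * n_sites];
            const double* y = &stack[(size_t)(sp - 1) * n_sites];
            const double* n = &stack[(size_t)sp * n_sites];
            for (int s = 0; s < n_sites; ++s) {
              c[s] = std::isnan(c[s]) ? NA_REAL : (c[s] != 0.0 ? y[s] : n[s]);
            }
            sp -= 2;
            break; }
          default: {  // binary operators
            double* a = &stack[(size_t)(sp - 1) * n_sites];
            const double* b = &stack[(size_t)sp * n_sites];
            switch (op[p]) {
            case OP_ADD: for (int s = 0; s < n_sites; ++s) a[s] += b[s]; break;
            case OP_SUB: for (int s = 0; s < n_sites; ++s) a[s] -= b[s]; break;
            case OP_MUL: for (int s = 0; s < n_sites; ++s) a[s] *= b[s]; break;
            case OP_DIV: for (int s = 0; s < n_sites; ++s) a[s] /= b[s]; break;
            case OP_POW:
              for (int s = 0; s < n_sites; ++s) a[s] = R_pow(a[s], b[s]);
              break;
            case OP_LT: case OP_LE: case OP_GT: case OP_GE:
            case OP_EQ: case OP_NE:
              for (int s = 0; s < n_sites; ++s) {
                if (std::isnan(a[s]) || std::isnan(b[s])) { a[s] = NA_REAL; continue; }
                bool r;
                switch (op[p]) {
                case OP_LT: r = a[s] < b[s]; break;
                case OP_LE: r = a[s] <= b[s]; break;
                case OP_GT: r = a[s] > b[s]; break;
                case OP_GE: r = a[s] >= b[s]; break;
                case OP_EQ: r = a[s] == b[s]; break;
                default: r = a[s] != b[s];
                }
                a[s] = r ? 1.0 : 0.0;
              }
              break;
            case OP_AND:
              for (int s = 0; s < n_sites; ++s) {
                if (std::isnan(a[s]) || std::isnan(b[s])) a[s] = NA_REAL;
                else a[s] = (a[s] != 0.0 && b[s] != 0.0) ? 1.0 : 0.0;
              }
              break;
            case OP_OR:
              for (int s = 0; s < n_sites; ++s) {
                if (std::isnan(a[s]) || std::isnan(b[s])) a[s] = NA_REAL;
                else a[s] = (a[s] != 0.0 || b[s] != 0.0) ? 1.0 : 0.0;
              }
              break;
            case OP_PMIN:
              for (int s = 0; s < n_sites; ++s) {
                if (std::isnan(a[s]) || std::isnan(b[s])) a[s] = NA_REAL;
                else if (b[s] < a[s]) a[s] = b[s];
              }
              break;
            case OP_PMAX:
              for (int s = 0; s < n_sites; ++s) {
                if (std::isnan(a[s]) || std::isnan(b[s])) a[s] = NA_REAL;
                else if (b[s] > a[s]) a[s] = b[s];
              }
              break;
            default:
              stop("corrupt rule bytecode (op %d)", op[p]);
            }
            --sp;
          }
          }
        }
        for (int s = 0; s < n_sites; ++s) res[s] = stack[s];
      }
      double* o = outp[v] + (size_t)day;
      for (int s = 0; s < n_sites; ++s) o[(size_t)s * n_days] = res[s];
    }
    std::copy(cur.begin(), cur.end(), prev.begin());
  }
  return out;
}
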