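#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair-type encoding shared with the R stack table: AT TA GC CG GT TG.
static inline int pair_code(char a, char b) {
    if (a == 'A' && b == 'T') return 0;
    if (a == 'T' && b == 'A') return 1;
    if (a == 'G' && b == 'C') return 2;
    if (a == 'C' && b == 'G') return 3;
    if (a == 'G' && b == 'T') return 4;
    if (a == 'T' && b == 'G') return 5;
    return -1;
}

struct Cell { int cnt; int e; };  // pair count, stack energy (x10, int)

static inline bool better(const Cell &a, const Cell &b) {
    // more pairs first, then lower stacking energy
    return a.cnt > b.cnt || (a.cnt == b.cnt && a.e < b.e);
}

// Maximum-pairing pseudoknot-free secondary structure (minimum hairpin
// loop 3); among count-optimal structures the one with the lowest
// nearest-neighbour stack energy is chosen, which keeps designed
// helices intact instead of equally-counted scattered pairings.
// `stack` is the 6x6 stack table (kcal/mol) in pair-code order.
// Returns the 1-based partner table (NA = unpaired).
// [[Rcpp::export(name = ".nussinovPairs")]]
IntegerVector nussinov_pairs(std::string seq, NumericMatrix stack) {
    const int n = (int)seq.size();
    IntegerVector partner(n, NA_INTEGER);
    if (n < 5) return partner;

    int st[6][6];
    for (int a = 0; a < 6; ++a)
        for (int b = 0; b < 6; ++b)
            st[a][b] = (int)lround(stack(a, b) * 10.0);

    const int NEG = -1000000000;
    std::vector<Cell> F(n * n), P(n * n);
    std::vector<int> cF(n * n), cP(n * n);
    // cF: -1 = j unpaired, k >= 0 = pair (k, j)
    // cP: -2 = stacked inner pair (i+1, j-1); -1 = inner j-1 unpaired;
    //     k >= 0 = inner pair (k, j-1)
#define IDX(i, j) ((i) * n + (j))
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
            F[IDX(i, j)].cnt = 0; F[IDX(i, j)].e = 0;
            P[IDX(i, j)].cnt = NEG; P[IDX(i, j)].e = 0;
            cF[IDX(i, j)] = -1; cP[IDX(i, j)] = -1;
        }

    for (int span = 4; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            // P[i][j]: structures where (i, j) is paired
            if (pair_code(seq[i], seq[j]) >= 0) {
                Cell best; best.cnt = NEG; best.e = 0;
                int choice = -1;
                // inner j-1 unpaired (or empty/short inner region)
                {
                    Cell cand;
                    if (j - 1 - (i + 1) >= 4) cand = F[IDX(i + 1, j - 2)];
                    else { cand.cnt = 0; cand.e = 0; }
                    // F[i+1][j-2] structures never pair j-1 by definition
                    best = cand; choice = -1;
                }
                // stacked inner pair (i+1, j-1)
                if (j - 1 - (i + 1) >= 4 &&
                    P[IDX(i + 1, j - 1)].cnt > NEG) {
                    Cell cand = P[IDX(i + 1, j - 1)];
                    int s1 = pair_code(seq[i], seq[j]);
                    int s2 = pair_code(seq[i + 1], seq[j - 1]);
                    cand.e += st[s1][s2];
                    if (better(cand, best)) { best = cand; choice = -2; }
                }
                // inner pair (k, j-1) with k > i+1 (no stack onto (i,j))
                for (int k = i + 2; k <= j - 5; ++k) {
                    if (pair_code(seq[k], seq[j - 1]) < 0) continue;
                    if (P[IDX(k, j - 1)].cnt <= NEG) continue;
                    Cell cand = P[IDX(k, j - 1)];
                    if (k - 1 - (i + 1) >= 4) {
                        cand.cnt += F[IDX(i + 1, k - 1)].cnt;
                        cand.e += F[IDX(i + 1, k - 1)].e;
                    }
                    if (better(cand, best)) { best = cand; choice = k; }
                }
                best.cnt += 1;
                P[IDX(i, j)] = best;
                cP[IDX(i, j)] = choice;
            }
            // F[i][j]: unconstrained
            Cell best = F[IDX(i, j - 1)];
            int choice = -1;
            for (int k = i; k <= j - 4; ++k) {
                if (P[IDX(k, j)].cnt <= NEG) continue;
                Cell cand = P[IDX(k, j)];
                if (k - 1 - i >= 0 && k - i >= 5) {
                    cand.cnt += F[IDX(i, k - 1)].cnt;
                    cand.e += F[IDX(i, k - 1)].e;
                } else if (k > i) {
                    // short prefix: no pairs possible, contributes 0
                }
                if (better(cand, best)) { best = cand; choice = k; }
            }
            F[IDX(i, j)] = best;
            cF[IDX(i, j)] = choice;
        }
    }

    // traceback over stored choices
    std::vector<std::pair<int, int> > stk;  // (i, j) intervals, F-state
    std::vector<std::pair<int, int> > pstk; // (i, j) pairs, P-state
    if (n >= 5) stk.push_back(std::make_pair(0, n - 1));
    while (!stk.empty() || !pstk.empty()) {
        if (!pstk.empty()) {
            int i = pstk.back().first, j = pstk.back().second;
            pstk.pop_back();
            partner[i] = j + 1;
            partner[j] = i + 1;
            int ch = cP[IDX(i, j)];
            if (ch == -2) {
                pstk.push_back(std::make_pair(i + 1, j - 1));
            } else if (ch == -1) {
                if (j - 2 >= i + 1 && j - 2 - (i + 1) >= 4)
                    stk.push_back(std::make_pair(i + 1, j - 2));
            } else {
                pstk.push_back(std::make_pair(ch, j - 1));
                if (ch - 1 >= i + 1 && ch - 1 - (i + 1) >= 4)
                    stk.push_back(std::make_pair(i + 1, ch - 1));
            }
            continue;
        }
        int i = stk.back().first, j = stk.back().second;
        stk.pop_back();
        if (j - i < 4) continue;
        int ch = cF[IDX(i, j)];
        if (ch == -1) {
            stk.push_back(std::make_pair(i, j - 1));
        } else {
            pstk.push_back(std::make_pair(ch, j));
            if (ch - 1 >= i && ch - 1 - i >= 4)
                stk.push_back(std::make_pair(i, ch - 1));
        }
    }
#undef IDX
    return partner;
}
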