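#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Watson-Crick + G.U wobble pairing on RNA
static inline bool can_pair(char a, char b) {
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization (Nussinov) with a minimum hairpin loop size.
// Returns the dot-bracket of one maximal structure; traceback is
// deterministic: position i is left unpaired whenever that is optimal,
// otherwise i pairs with the smallest admissible k.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop) {
    int n = seq.size();
    for (int i = 0; i < n; ++i) {
        char c = seq[i];
        if (c == 'T') seq[i] = 'U';
        else if (c != 'A' && c != 'C' && c != 'G' && c != 'U' && c != 'N')
            stop("invalid character '%s' at position %d",
                 std::string(1, c).c_str(), i + 1);
    }
    std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = dp[i + 1][j]; // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (can_pair(seq[i], seq[k])) {
                    int v = 1 + (k - i - 1 > 0 ? dp[i + 1][k - 1] : 0) +
                            (k + 1 <= j ? dp[k + 1][j] : 0);
                    if (v > best) best = v;
                }
            }
            dp[i][j] = best;
        }
    }
    std::string db(n, '.');
    std::stack<std::pair<int, int> > st;
    if (n > 1) st.push(std::make_pair(0, n - 1));
    while (!st.empty()) {
        int i = st.top().first, j = st.top().second;
        st.pop();
        if (i >= j || j - i < min_loop + 1) continue;
        if (dp[i][j] == dp[i + 1][j]) { // leave i unpaired
            st.push(std::make_pair(i + 1, j));
            continue;
        }
        for (int k = i + min_loop + 1; k <= j; ++k) {
            if (can_pair(seq[i], seq[k])) {
                int v = 1 + (k - i - 1 > 0 ? dp[i + 1][k - 1] : 0) +
                        (k + 1 <= j ? dp[k + 1][j] : 0);
                if (v == dp[i][j]) {
                    db[i] = '(';
                    db[k] = ')';
                    if (k - i - 1 > 0) st.push(std::make_pair(i + 1, k - 1));
                    if (k + 1 <= j) st.push(std::make_pair(k + 1, j));
                    break;
                }
            }
        }
    }
    int pairs = 0;
    for (int i = 0; i < n; ++i) if (db[i] == '(') ++pairs;
    return List::create(_["pairing"] = db, _["pair_count"] = pairs);
}
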