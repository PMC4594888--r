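#include <Rcpp.h>
#include <vector>
#include <string>

// Base-pair maximisation folding score (Nussinov-style dynamic program):
// -1 per canonical pair (Watson-Crick or G:U wobble), hairpin loops of at
// least 3 unpaired nucleotides. Used as the built-in approximate folding
// backend; a thermodynamic engine can be injected instead.

static bool canPair(char a, char b) {
    switch (a) {
    case 'A': return b == 'U';
    case 'U': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'U';
    case 'C': return b == 'G';
    default: return false;
    }
}

// [[Rcpp::export(name = ".nussinovScore")]]
double nussinovScore(std::string seq) {
    int n = seq.size();
    for (int i = 0; i < n; ++i) {
        char &c = seq[i];
        c = toupper(c);
        if (c == 'T') c = 'U';
    }
    if (n < 5) return 0.0;
    std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
    for (int len = 5; len <= n; ++len) {         // j - i + 1
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = N[i][j - 1];              // j unpaired
            for (int k = i; k <= j - 4; ++k) {   // j pairs k, loop >= 3
                if (!canPair(seq[k], seq[j])) continue;
                int left = (k > i) ? N[i][k - 1] : 0;
                int inner = N[k + 1][j - 1];
                int cand = left + inner + 1;
                if (cand > best) best = cand;
            }
            N[i][j] = best;
        }
    }
    return -static_cast<double>(N[0][n - 1]);
}
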