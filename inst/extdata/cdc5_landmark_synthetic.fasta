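>cdc5_landmark_synthetic
PDEVMHLRDELCDAKCYTACMDNVLLQPGAGWDKDDNLLSSNIRTHGEGKWLSLPKRCRR
KGQCGKPGRWRLINYAQVDMYQLLWSDEEAKIALAHPKYKHVKWLYIKKSLPGEYDNAIK
ISWNITTDRISSDRHGIPFVRGETQDIGQQYHTLAVTVYTNIDGAGVQSIGVVLPNEVLL
PALLTNVRDKFCRWCKKGLLVDPCGFEEPAIVVADQYTTGNTFKVMASEMVNRRLQKPDK
QIYTRGQASKQPLHAATYLTLNREWSTWDQRSTGKNYTVSTAPEYSTSQSRTTDSIESDA
DETVQKGVLVRVDVQRHPEKLGLQPAYLPPFGAMEETPEEGGERGVFYKELAQHLMIHDI
WSNRLKESPFDDACITAGKDFICMAPSRGDVLAQTISMVKVWKPLSLWPIQQKSLKQAQQ
ELNCFFAGLGDGYLFTSGAEPTVGPLKDD
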