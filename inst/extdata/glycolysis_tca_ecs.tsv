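ec_number	kegg_ids	step
2.7.1.1	K00844	hexokinase
5.3.1.9	K01810	glucose-6-phosphate isomerase
2.7.1.11	K00850	6-phosphofructokinase
4.1.2.13	K01623	fructose-bisphosphate aldolase
5.3.1.1	K01803	triosephosphate isomerase
1.2.1.12	K00134	glyceraldehyde-3-phosphate dehydrogenase
2.7.2.3	K00927	phosphoglycerate kinase
5.4.2.11	K01834	phosphoglycerate mutase
4.2.1.11	K01689	enolase
2.7.1.40	K00873	pyruvate kinase
2.3.3.1	K01647	citrate synthase
4.2.1.3	K01681	aconitase
1.1.1.42	K00031	isocitrate dehydrogenase
1.2.4.2	K00164	2-oxoglutarate dehydrogenase E1
6.2.1.5	K01902	succinyl-CoA synthetase alpha
1.3.5.1	K00234	succinate dehydrogenase flavoprotein
4.2.1.2	K01679	fumarase class II
1.1.1.37	K00024	malate dehydrogenase
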