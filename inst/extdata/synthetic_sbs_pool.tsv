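context	SYN1	SYN2	SYN3	SYN4	SYN5	SYN6	SYN7	SYN8	BG1	BG2
A[C>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0108984285	0.0151171235
A[C>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0116079300	0.0150547851
A[C>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0122882209	0.0149514600
A[C>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0129254413	0.0148080014
C[C>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0135066087	0.0146255943
C[C>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0140198827	0.0144057450
C[C>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0144548063	0.0141502693
C[C>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0148025184	0.0138612770
G[C>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0150559350	0.0135411549
G[C>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152098930	0.0131925469
G[C>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152612559	0.0128183318
G[C>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152089772	0.0124216004
T[C>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0150541220	0.0120056292
T[C>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.15	0.00	0.0147998452	0.0115738535
T[C>A]G	0.00	0.00	0.00	0.00	0.60	0.00	0.00	0.00	0.0144513273	0.0111298393
T[C>A]T	0.25	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0140156689	0.0106772536
A[C>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0135017458	0.0102198341
A[C>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0129200285	0.0097613588
A[C>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0122823684	0.0093056139
A[C>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0116017571	0.0088563633
C[C>G]A	0.00	0.00	0.60	0.00	0.00	0.00	0.00	0.00	0.0108920609	0.0084173174
C[C>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0101677387	0.0079921021
C[C>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0094435477	0.0075842292
C[C>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0087342419	0.0071970671
G[C>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0080542726	0.0068338134
G[C>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0074174929	0.0064974681
G[C>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0068368764	0.0061908091
G[C>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0063242522	0.0059163688
T[C>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0058900642	0.0056764139
T[C>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.60	0.0055431584	0.0054729262
T[C>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0052906025	0.0053075860
T[C>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0051375418	0.0051817591
A[C>T]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0050870948	0.0050964845
A[C>T]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0051402892	0.0050524665
A[C>T]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0052960414	0.0050500687
A[C>T]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0055511780	0.0050893108
C[C>T]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0059005011	0.0051698687
C[C>T]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0063368937	0.0052910772
C[C>T]G	0.00	0.00	0.00	0.00	0.00	0.00	0.60	0.00	0.0068514650	0.0054519352
C[C>T]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0074337314	0.0056511142
G[C>T]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0080718300	0.0058869693
G[C>T]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0087527607	0.0061575526
G[C>T]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0094626505	0.0064606293
G[C>T]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0101870364	0.0067936965
T[C>T]A	0.00	0.00	0.00	0.00	0.15	0.00	0.00	0.00	0.0109111602	0.0071540034
T[C>T]C	0.00	0.00	0.00	0.25	0.00	0.00	0.00	0.00	0.0116202690	0.0075385743
T[C>T]G	0.00	0.00	0.00	0.00	0.00	0.25	0.00	0.00	0.0122999158	0.0079442332
T[C>T]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0129362537	0.0083676298
A[T>A]A	0.00	0.60	0.00	0.00	0.00	0.00	0.00	0.00	0.0135163184	0.0088052673
A[T>A]C	0.00	0.00	0.00	0.15	0.00	0.00	0.00	0.00	0.0140282919	0.0092535314
A[T>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0144617436	0.0097087201
A[T>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0148078426	0.0101670740
C[T>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0150595375	0.0106248076
C[T>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152117005	0.0110781406
C[T>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152612315	0.0115233292
C[T>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0152071214	0.0119566965
G[T>A]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0150504726	0.0123746634
G[T>A]C	0.00	0.00	0.00	0.00	0.00	0.60	0.00	0.00	0.0147944766	0.0127737782
G[T>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.25	0.0144443489	0.0131507445
G[T>A]T	0.60	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0140072228	0.0135024492
T[T>A]A	0.00	0.15	0.00	0.00	0.00	0.00	0.00	0.00	0.0134920041	0.0138259875
T[T>A]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0129091897	0.0141186874
T[T>A]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0122706533	0.0143781316
T[T>A]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0115894044	0.0146021774
A[T>C]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0108793222	0.0147889745
A[T>C]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0101548737	0.0149369801
A[T>C]G	0.00	0.00	0.00	0.00	0.25	0.00	0.00	0.00	0.0094308183	0.0150449719
A[T>C]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0087219076	0.0151120580
C[T>C]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0080425845	0.0151376844
C[T>C]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0074066893	0.0151216394
C[T>C]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0068271774	0.0150640555
C[T>C]T	0.00	0.25	0.00	0.00	0.00	0.00	0.00	0.00	0.0063158553	0.0149654083
G[T>C]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0058831406	0.0148265126
G[T>C]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0055378491	0.0146485153
G[T>C]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0052870156	0.0144328866
G[T>C]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0051357504	0.0141814073
T[T>C]A	0.00	0.00	0.00	0.00	0.00	0.00	0.25	0.00	0.0050871355	0.0138961543
T[T>C]C	0.00	0.00	0.25	0.00	0.00	0.00	0.00	0.00	0.0051421611	0.0135794835
T[T>C]G	0.00	0.00	0.15	0.00	0.00	0.00	0.00	0.00	0.0052997063	0.0132340101
T[T>C]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0055565613	0.0128625873
A[T>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.15	0.0059074931	0.0124682826
A[T>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0063453520	0.0120543526
A[T>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0068612173	0.0116242157
A[T>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0074445789	0.0111814244
C[T>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0080835519	0.0107296355
C[T>G]C	0.00	0.00	0.00	0.00	0.00	0.15	0.00	0.00	0.0087651180	0.0102725804
C[T>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0094753914	0.0098140336
C[T>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0101999015	0.0093577823
G[T>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0109238873	0.0089075945
G[T>G]C	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0116325988	0.0084671882
G[T>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0123115970	0.0080402007
G[T>G]T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0129470485	0.0076301583
T[T>G]A	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0135260068	0.0072404474
T[T>G]C	0.00	0.00	0.00	0.60	0.00	0.00	0.00	0.00	0.0140366765	0.0068742867
T[T>G]G	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0144686536	0.0065347001
T[T>G]T	0.15	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.0148131371	0.0062244922
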