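length_um,tau_s
2,0.00552312291831757
2.23889536947276,0.00766128412774014
2.50632623772327,0.00771653703137729
2.80570110401335,0.010038881731296
3.14083560495004,0.0187095714492652
3.5160011460989,0.0174876374305765
3.93597934253086,0.0315242790608172
4.40612296216638,0.0367751821269965
4.93242414866094,0.0433749561161748
5.52159079335629,0.0493975316410382
6.18113202968438,0.0672265193914983
6.91945393968005,0.0967076328396789
7.74596669241483,0.109643204808506
8.67120447986887,0.181897182032102
9.70695977886492,0.22080971168134
10.8664336502795,0.36893676232271
12.1644039911468,0.506803594047515
13.6174138840872,0.861522140641563
15.2439824446384,1.00677194463748
17.0648408538125,1.46909021003469
19.1031965841951,2.17675607317582
21.3850291872411,3.60817161340777
23.9394214116769,5.11973238538302
26.7989298732301,8.77445982220151
30,12.8827405339708
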