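0.0000000000 0.0738336113 -0.0677931694 0.3915541478 -0.4495752426 -0.2940210131 0.4915618742 -0.5171163459 0.2951634080 0.1233796546 -0.1445206216 0.7498397271 0.6878369120 -0.6910787308 -0.8196231917 -0.3366799761 0.5185437705 -0.4575637165 -0.7921310438 0.0312212586 0.0890428781 0.8440025461 0.4888751289 0.9599638364 -0.9413235272 -0.6558298618 0.8336699544 -0.9738497418 -0.2463685716 -0.3010505945 0.7206087638
0.0000000000 -0.2084786951 0.2448408941 0.1384752545 -0.0600650597 -0.4713404909 -0.3871130071 0.3767588596 0.5954357542 -0.6581730031 0.6550830311 -0.0468529367 0.4107411892 -0.4394945790 0.0177760820 -0.7971184435 -0.7376656340 0.7830706338 0.4594942219 0.9203900404 -0.9271708870 -0.3999198731 0.8024704626 0.0869212559 -0.2640753350 -0.7336438467 0.5250984410 0.2121732830 -0.9686815179 0.9532791695 -0.6933252283
0.0000000000 0.9752359876 0.9671902723 0.9096757407 0.8912206741 0.8314985180 0.7800707939 0.7685333087 0.7472180573 0.7426881976 0.7416063729 0.6599584730 0.5984747764 0.5738072001 0.5726271339 0.5012472251 0.4323907614 0.4212313234 0.4017380609 0.3897530072 0.3639031632 0.3573846629 0.3421144032 0.2662970675 0.2101766745 0.1779154252 0.1710731845 0.0812353270 0.0309619739 0.0250472453 0.0048101312
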